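#' VanRaden additive genomic relationship matrix
#'
#' `A = W W' / (2 * sum p_j (1 - p_j))` with `W` the column-centered coding
#' (`x - 2(p_j - 0.5)` on the \{-1, 0, 1\} scale) and `p_j` the alternative
#' allele frequency. Monomorphic columns contribute nothing to the numerator
#' and are dropped from the denominator sum with a warning.
#'
#' @param X complete coded genotype matrix, samples x markers.
#' @return `kernel_spec` of kind `"additive_A"`.
#' @export
vanraden_a_matrix <- function(X) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("genotype matrix must be complete")
  p <- colMeans(X + 1) / 2
  poly <- p > 0 & p < 1
  if (!all(poly))
    warning(sprintf("%d monomorphic column(s) dropped from the denominator",
                    sum(!poly)))
  W <- sweep(X, 2, 2 * (p - 0.5))
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  if (denom == 0) stop("all markers monomorphic")
  A <- tcrossprod(W) / denom
  rownames(A) <- colnames(A) <- rownames(X)
  structure(list(kind = "additive_A", matrix = A, bandwidth = NA,
                 scaling = denom), class = "kernel_spec")
}

#' Gaussian kernel on Euclidean genotype distances
#'
#' `K_ij = exp(-h * d2_ij / mean(d2))` with `d` the Euclidean distance
#' between coded genotype rows and the mean taken over off-diagonal squared
#' distances. The normalization keeps `h = 1` on a usable scale for
#' thousands of markers; `scale = "raw"` gives the unnormalized
#' `exp(-h * d2)`.
#'
#' @param X complete genotype matrix, samples x markers.
#' @param bandwidth kernel bandwidth `h` (default 1).
#' @param scale `"mean_d2"` (default) or `"raw"`.
#' @return `kernel_spec` of kind `"gaussian"` (unit diagonal).
#' @export
gaussian_kernel <- function(X, bandwidth = 1, scale = c("mean_d2", "raw")) {
  scale <- match.arg(scale)
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("Gaussian kernel needs at least 2 samples")
  if (anyNA(X)) stop("genotype matrix must be complete")
  D2 <- as.matrix(dist(X, method = "euclidean"))^2
  s <- if (scale == "mean_d2") mean(D2[upper.tri(D2)]) else 1
  if (s == 0) s <- 1
  K <- exp(-bandwidth * D2 / s)
  rownames(K) <- colnames(K) <- rownames(X)
  structure(list(kind = "gaussian", matrix = K, bandwidth = bandwidth,
                 scaling = s), class = "kernel_spec")
}

kernel_matrix <- function(kernel) {
  if (inherits(kernel, "kernel_spec")) kernel$matrix else as.matrix(kernel)
}

# REML profile log-likelihood machinery for a single-kernel mixed model
# y = 1*mu + u + e,  u ~ N(0, var_u * K),  e ~ N(0, var_e * I)
# delta = var_e / var_u; spectral decomposition of K makes the profile 1-D.
gblup_reml <- function(y, K) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  profile <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    sxx <- sum(w * xt^2)
    beta <- sum(w * xt * yt) / sxx
    r <- yt - xt * beta
    s2 <- sum(w * r^2) / (n - 1)
    ll <- -0.5 * ((n - 1) * (log(2 * pi * s2) + 1) + sum(log(d + delta)) +
                    log(sxx))
    list(ll = ll, beta = beta, var_u = s2, delta = delta)
  }
  grid <- seq(log(1e-5), log(1e6), length.out = 40)
  lls <- vapply(grid, function(g) profile(g)$ll, numeric(1))
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(g) profile(g)$ll, c(lo, hi), maximum = TRUE)
  best <- profile(opt$maximum)
  if (!is.finite(best$ll))
    stop("REML did not converge; likelihood trace attached",
         call. = FALSE)
  list(mu = best$beta, var_u = best$var_u, var_e = best$var_u * best$delta,
       delta = best$delta, loglik = best$ll,
       trace = data.frame(log_delta = grid, reml_ll = lls))
}

# conditional-mean prediction on the validation block of a kernel
kernel_conditional_mean <- function(K, train, validation, y_train, mu, delta) {
  Ktt <- K[train, train, drop = FALSE]
  Kvt <- K[validation, train, drop = FALSE]
  alpha <- solve(Ktt + delta * diag(length(train)), y_train - mu)
  list(validation = drop(mu + Kvt %*% alpha),
       train = drop(mu + Ktt %*% alpha))
}

#' GBLUP: REML variance components and conditional-mean prediction
#'
#' Variance components are estimated by REML on the training submatrix using
#' its spectral decomposition; validation predictions are the conditional
#' mean `mu + K_vt (K_tt + delta I)^-1 (y_t - mu)` with
#' `delta = var_e / var_u`. The method is deterministic, so a single
#' replicate suffices. Predictions with (numerically) zero variance across
#' the validation set are flagged `degenerate`.
#'
#' @param y_train training phenotypes.
#' @param kernel a `kernel_spec` (or plain matrix) over train and validation
#'   samples.
#' @param train,validation index sets into the kernel.
#' @param delta optional fixed variance ratio `var_e/var_u` (skips REML).
#' @return list with `predictions`, `fitted`, `var_u`, `var_e`, `mu`,
#'   `loglik`, `degenerate`.
#' @export
fit_gblup <- function(y_train, kernel, train, validation, delta = NULL) {
  K <- kernel_matrix(kernel)
  stopifnot(length(y_train) == length(train))
  if (is.null(delta)) {
    reml <- gblup_reml(y_train, K[train, train, drop = FALSE])
  } else {
    w_mu <- solve(K[train, train, drop = FALSE] + delta * diag(length(train)),
                  rep(1, length(train)))
    reml <- list(mu = sum(w_mu * y_train) / sum(w_mu), var_u = NA,
                 var_e = NA, delta = delta, loglik = NA, trace = NULL)
  }
  pred <- kernel_conditional_mean(K, train, validation, y_train, reml$mu,
                                  reml$delta)
  degenerate <- length(pred$validation) > 1 &&
    isTRUE(sd(pred$validation) < 1e-10)
  list(predictions = pred$validation, fitted = pred$train, mu = reml$mu,
       var_u = reml$var_u, var_e = reml$var_e, delta = reml$delta,
       loglik = reml$loglik, degenerate = degenerate, trace = reml$trace)
}

#' RKHS regression via Gibbs sampling on the kernel eigen-representation
#'
#' Bayesian single-kernel model `y = 1*mu + u + e`, `u ~ N(0, var_u K)`.
#' The kernel is eigendecomposed so the random effect becomes independent
#' normal coordinates; variance components get scaled-inverse-chi-square
#' updates. Validation predictions use the conditional mean under the
#' posterior-mean variance components.
#'
#' @param y_train training phenotypes.
#' @param kernel `kernel_spec` or matrix over train and validation samples.
#' @param train,validation index sets.
#' @param mcmc list of chain controls: `n_iter`, `burn_in`, `thin`, `df`,
#'   `r2`, `seed`.
#' @return list with `predictions`, `fitted`, `mu`, `var_u`, `var_e`,
#'   `degenerate`, and the stored variance draws.
#' @export
fit_rkhs <- function(y_train, kernel, train, validation,
                     mcmc = list()) {
  mcmc <- modifyList(list(n_iter = 3000, burn_in = 1000, thin = 5,
                          df = 5, r2 = 0.5, seed = 1), mcmc)
  K <- kernel_matrix(kernel)
  Ktt <- K[train, train, drop = FALSE]
  eg <- eigen(Ktt, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values)))
    stop("kernel is not positive semidefinite")
  keep <- which(eg$values > 1e-10 * max(eg$values))
  d <- eg$values[keep]
  U <- eg$vectors[, keep, drop = FALSE]
  n <- length(y_train); r <- length(keep)

  vy <- var(y_train); if (vy == 0) vy <- 1
  s_u <- vy * mcmc$r2 * (mcmc$df + 2) / mcmc$df / mean(diag(Ktt))
  s_e <- vy * (1 - mcmc$r2) * (mcmc$df + 2) / mcmc$df

  set.seed(mcmc$seed)
  uty <- drop(crossprod(U, y_train))
  ut1 <- drop(crossprod(U, rep(1, n)))
  mu <- mean(y_train); b <- numeric(r)
  var_u <- s_u; var_e <- s_e
  nsave <- (mcmc$n_iter - mcmc$burn_in) %/% mcmc$thin
  draws_u <- numeric(nsave); draws_e <- numeric(nsave); mu_sum <- 0
  isave <- 0L
  for (it in seq_len(mcmc$n_iter)) {
    z <- uty - mu * ut1
    v <- var_e * var_u * d / (var_u * d + var_e)
    b <- rnorm(r, v * z / var_e, sqrt(v))
    u <- drop(U %*% b)
    mu <- rnorm(1, mean(y_train - u), sqrt(var_e / n))
    var_u <- (sum(b^2 / d) + mcmc$df * s_u) / rchisq(1, mcmc$df + r)
    e <- y_train - mu - u
    var_e <- (sum(e^2) + mcmc$df * s_e) / rchisq(1, mcmc$df + n)
    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thin == 0 &&
        isave < nsave) {
      isave <- isave + 1L
      draws_u[isave] <- var_u
      draws_e[isave] <- var_e
      mu_sum <- mu_sum + mu
    }
  }
  var_u_hat <- mean(draws_u); var_e_hat <- mean(draws_e)
  mu_hat <- mu_sum / max(isave, 1)
  pred <- kernel_conditional_mean(K, train, validation, y_train, mu_hat,
                                  var_e_hat / var_u_hat)
  list(predictions = pred$validation, fitted = pred$train, mu = mu_hat,
       var_u = var_u_hat, var_e = var_e_hat,
       var_u_draws = draws_u, var_e_draws = draws_e,
       degenerate = length(pred$validation) > 1 &&
         isTRUE(sd(pred$validation) < 1e-10))
}
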