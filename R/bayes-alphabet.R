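#' Specification of a Bayesian whole-genome regression model
#'
#' Families share the linear model `y = 1*mu + X beta + e` and differ only in
#' the marker-effect prior: a common normal variance (BRR), per-marker
#' scaled-inverse-chi-square variances (BayesA), per-marker variances with an
#' exclusion indicator (BayesB), a common variance with an indicator
#' (BayesC), or double-exponential shrinkage in the Park-Casella
#' parameterization (BL). Prior scales default to the customary R2 = 0.5
#' variance partition; degrees of freedom default to 5.
#'
#' @param family one of `"BRR"`, `"BayesA"`, `"BayesB"`, `"BayesC"`, `"BL"`.
#' @param n_iter,burn_in,thin chain length controls (`n_iter > burn_in`).
#' @param df_beta,df_e prior degrees of freedom for marker / residual
#'   variances.
#' @param scale_beta,scale_e prior scales; when NULL they are solved from
#'   `r2` and the data inside [fit_bayes()].
#' @param r2 prior variance partition used to solve default scales.
#' @param pi prior exclusion probability for BayesB/BayesC (`pi = 0` means no
#'   exclusion; as `pi -> 1` all markers drop out).
#' @param bl_shape,bl_rate gamma prior on the squared BL shrinkage rate
#'   (`bl_rate = NULL` solved from `r2`).
#' @param var_b_fixed,var_e_fixed optional fixed variance components (used
#'   mainly for conjugate closed-form checks); fixing both turns the sampler
#'   into a pure Gaussian Gibbs sampler.
#' @param sigma2_a how [genomic_heritability()] forms the additive variance:
#'   `"marker_sum"` (posterior marker variance times the summed column
#'   variances) or `"var_xbeta"` (variance of the fitted genetic values).
#' @param seed chain seed.
#' @return object of class `bayes_spec`.
#' @export
bayes_spec <- function(family = c("BRR", "BayesA", "BayesB", "BayesC", "BL"),
                       n_iter = 20000, burn_in = 5000, thin = 5,
                       df_beta = 5, df_e = 5, scale_beta = NULL,
                       scale_e = NULL, r2 = 0.5, pi = 0.5,
                       bl_shape = 1.1, bl_rate = NULL,
                       var_b_fixed = NULL, var_e_fixed = NULL,
                       sigma2_a = c("marker_sum", "var_xbeta"), seed = 1) {
  family <- match.arg(family)
  sigma2_a <- match.arg(sigma2_a)
  if (!(n_iter > burn_in && burn_in >= 0)) stop("need n_iter > burn_in >= 0")
  if (family %in% c("BayesB", "BayesC") && (pi < 0 || pi >= 1))
    stop("pi must be in [0, 1)")
  structure(as.list(environment()), class = "bayes_spec")
}

#' Fit a Bayesian alphabet model by Gibbs sampling
#'
#' @param y numeric response (no missing values).
#' @param X coded genotype matrix, samples x markers, complete.
#' @param spec a [bayes_spec()].
#' @return `bayes_fit`: posterior means of `mu` and `beta`, thinned draws of
#'   the variance components, marker inclusion probabilities (BayesB/C), and
#'   the scaling metadata needed by [predict.bayes_fit()].
#' @export
fit_bayes <- function(y, X, spec = bayes_spec()) {
  stopifnot(inherits(spec, "bayes_spec"))
  X <- as.matrix(X)
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  if (anyNA(X)) stop("genotype matrix must be complete")
  if (length(y) != nrow(X)) stop("dimension mismatch between y and X")

  col_var <- apply(X, 2, var)
  active <- which(col_var > 0)
  if (length(active) < ncol(X))
    warning(sprintf("%d zero-variance marker(s): effects fixed at 0",
                    ncol(X) - length(active)))

  vy <- var(y)
  if (vy == 0) vy <- 1
  msx <- sum(col_var[active])
  if (msx == 0) msx <- 1
  r2 <- spec$r2
  prop_in <- if (spec$family %in% c("BayesB", "BayesC")) 1 - spec$pi else 1
  scale_b <- spec$scale_beta %||%
    (vy * r2 / (msx * max(prop_in, 1e-3)) * (spec$df_beta + 2) / spec$df_beta)
  scale_e <- spec$scale_e %||% (vy * (1 - r2) * (spec$df_e + 2) / spec$df_e)
  lambda2_0 <- 2 * (1 - r2) * msx / max(r2, 1e-3)
  bl_rate <- spec$bl_rate %||% (spec$bl_shape / lambda2_0)

  set.seed(spec$seed)
  res <- .gibbs_alphabet_cpp(
    as.numeric(y), X, spec$family,
    as.integer(spec$n_iter), as.integer(spec$burn_in), as.integer(spec$thin),
    spec$df_beta, scale_b, spec$df_e, scale_e,
    if (spec$family %in% c("BayesB", "BayesC")) spec$pi else 0,
    spec$bl_shape, bl_rate, lambda2_0,
    !is.null(spec$var_b_fixed), spec$var_b_fixed %||% 0,
    !is.null(spec$var_e_fixed), spec$var_e_fixed %||% 0,
    as.integer(active - 1L))

  structure(list(mu = res$mu, beta = as.numeric(res$beta),
                 inclusion_prob = as.numeric(res$inclusion_prob),
                 var_e_draws = as.numeric(res$var_e_draws),
                 var_b_draws = as.numeric(res$var_b_draws),
                 n_draws = res$n_draws, family = spec$family,
                 sum_col_var = msx, spec = spec,
                 marker_names = colnames(X)),
            class = "bayes_fit")
}

#' @export
print.bayes_fit <- function(x, ...) {
  cat(sprintf("bayes_fit [%s]: %d markers, %d stored draws\n", x$family,
              length(x$beta), x$n_draws))
  cat(sprintf("  posterior means: var_e = %.4g, var_b = %.4g\n",
              mean(x$var_e_draws), mean(x$var_b_draws)))
  invisible(x)
}

#' Predict from a fitted Bayesian alphabet model
#'
#' `y_hat = mu + X_new beta` with posterior-mean coefficients.
#'
#' @param object a `bayes_fit`.
#' @param X_new matrix with the same marker columns as the training matrix.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.bayes_fit <- function(object, X_new, ...) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(object$beta))
    stop("X_new column count does not match the fitted model")
  drop(object$mu + X_new %*% object$beta)
}

#' Narrow-sense genomic heritability from Bayesian ridge regression
#'
#' `h2 = sigma2_a / sigma2_y`. Per chain the additive genomic variance is the
#' posterior mean of the common marker-effect variance times the summed
#' column variances of the coded genotypes (or `var(X beta_hat)` with
#' `sigma2_a = "var_xbeta"` in the spec), and `sigma2_y = sigma2_a +
#' sigma2_e` (or the raw sample variance of `y` with `total =
#' "sample_var"`). The estimate is averaged over `n_chains` independent
#' chains with distinct seeds.
#'
#' @param y phenotypes; samples with missing values are removed first.
#' @param X coded genotype matrix (rows aligned with `y`).
#' @param spec a [bayes_spec()]; family is forced to BRR.
#' @param n_chains number of independent chains (default 10).
#' @param total `"components"` (`sigma2_a + sigma2_e`) or `"sample_var"`.
#' @return list with `h2` (mean over chains), `per_chain`, and the variance
#'   components per chain.
#' @export
genomic_heritability <- function(y, X, spec = bayes_spec("BRR"),
                                 n_chains = 10,
                                 total = c("components", "sample_var")) {
  total <- match.arg(total)
  if (n_chains < 1) stop("n_chains must be at least 1")
  keep <- which(!is.na(y))
  y <- y[keep]
  X <- as.matrix(X)[keep, , drop = FALSE]
  spec$family <- "BRR"
  per_chain <- vapply(seq_len(n_chains), function(ch) {
    sp <- spec
    sp$seed <- substream_seed(spec$seed, "h2_chain", ch)
    fit <- fit_bayes(y, X, sp)
    var_b <- mean(fit$var_b_draws)
    var_e <- mean(fit$var_e_draws)
    var_a <- if (spec$sigma2_a == "var_xbeta") {
      var(drop(X %*% fit$beta))
    } else var_b * fit$sum_col_var
    var_y <- if (total == "sample_var") var(y) else var_a + var_e
    c(h2 = var_a / var_y, var_a = var_a, var_e = var_e)
  }, c(h2 = 0, var_a = 0, var_e = 0))
  list(h2 = mean(per_chain["h2", ]), per_chain = per_chain["h2", ],
       var_a = per_chain["var_a", ], var_e = per_chain["var_e", ],
       n = length(y))
}
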