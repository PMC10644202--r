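# Minimal convolutional network for genomic prediction, trained by Adam on
# squared error with manual backpropagation. One conv block (valid padding,
# stride 1) -> ReLU -> non-overlapping mean pooling -> channel average (the
# phase axis of 2-D inputs is summarized here, i.e. in the final pooling
# stage) -> dense -> ReLU -> dropout -> linear output.
#
# Channels share convolution weights, so a 2-channel input whose channels
# are identical is mathematically equivalent to the 1-channel network run on
# the common channel.

cnn_init <- function(p, params) {
  kw <- params$kernel_size
  f <- params$n_filters
  l1 <- p - kw + 1
  if (l1 < 1) stop("kernel_size exceeds the number of SNPs")
  l2 <- max(1L, l1 %/% params$pool_size)
  h <- params$dense_units
  # He-style fan-in scaling
  list(Wc = matrix(rnorm(kw * f, 0, sqrt(2 / kw)), kw, f),
       bc = numeric(f),
       W1 = matrix(rnorm(l2 * f * h, 0, sqrt(2 / (l2 * f))), l2 * f, h),
       b1 = numeric(h),
       w2 = matrix(rnorm(h, 0, sqrt(1 / h)), h, 1),
       b2 = 0,
       l1 = l1, l2 = l2)
}

# im2col: rows = (sample, position) pairs, columns = kernel taps
cnn_cols <- function(X, kw, l1) {
  n <- nrow(X)
  out <- matrix(0, n * l1, kw)
  for (k in seq_len(kw)) out[, k] <- as.vector(X[, k:(k + l1 - 1)])
  out
}

cnn_forward <- function(channels, w, params, drop_mask = NULL) {
  n <- nrow(channels[[1]])
  f <- params$n_filters
  ps <- params$pool_size
  l1 <- w$l1; l2 <- w$l2
  ch <- lapply(channels, function(X) {
    Xc <- cnn_cols(X, params$kernel_size, l1)
    Z <- sweep(Xc %*% w$Wc, 2, w$bc, "+") # (n*l1) x f
    A <- pmax(Z, 0)
    # mean-pool non-overlapping windows along the position axis
    P <- matrix(0, n * l2, f)
    for (s in seq_len(ps)) {
      pos <- (seq_len(l2) - 1) * ps + s
      P <- P + A[rep((pos - 1) * n, each = n) + seq_len(n), , drop = FALSE]
    }
    P <- P / ps
    list(Xc = Xc, Z = Z, P = P)
  })
  Pm <- Reduce(`+`, lapply(ch, `[[`, "P")) / length(ch)
  M <- matrix(Pm, n, l2 * f) # flatten (position-major then filter)
  D <- sweep(M %*% w$W1, 2, w$b1, "+")
  Dr <- pmax(D, 0)
  Dd <- if (is.null(drop_mask)) Dr else Dr * drop_mask
  out <- drop(Dd %*% w$w2 + w$b2)
  list(ch = ch, M = M, D = D, Dd = Dd, out = out)
}

cnn_backward <- function(channels, w, params, fw, d_out, drop_mask) {
  n <- nrow(channels[[1]])
  f <- params$n_filters
  ps <- params$pool_size
  l1 <- w$l1; l2 <- w$l2
  g <- list()
  g$b2 <- sum(d_out)
  g$w2 <- crossprod(fw$Dd, d_out)
  dDd <- tcrossprod(d_out, w$w2) # n x h
  if (!is.null(drop_mask)) dDd <- dDd * drop_mask
  dD <- dDd * (fw$D > 0)
  g$W1 <- crossprod(fw$M, dD)
  g$b1 <- colSums(dD)
  dM <- tcrossprod(dD, w$W1) # n x (l2*f)
  dPm <- matrix(dM, n * l2, f)
  g$Wc <- matrix(0, params$kernel_size, f)
  g$bc <- numeric(f)
  nch <- length(channels)
  for (ci in seq_len(nch)) {
    dP <- dPm / nch
    # un-pool: spread gradient evenly over the pooled window
    dA <- matrix(0, n * l1, f)
    for (s in seq_len(ps)) {
      pos <- (seq_len(l2) - 1) * ps + s
      dA[rep((pos - 1) * n, each = n) + seq_len(n), ] <- dP / ps
    }
    dZ <- dA * (fw$ch[[ci]]$Z > 0)
    g$Wc <- g$Wc + crossprod(fw$ch[[ci]]$Xc, dZ)
    g$bc <- g$bc + colSums(dZ)
  }
  g
}

cnn_fit <- function(channels, y, params) {
  defaults <- list(n_filters = 8, kernel_size = 5, pool_size = 2,
                   dense_units = 16, dropout = 0.2, learning_rate = 1e-3,
                   batch_size = 32, epochs = 30, patience = 8)
  params <- modifyList(defaults, params)
  params$n_filters <- as.integer(round(params$n_filters))
  params$kernel_size <- as.integer(round(params$kernel_size))
  params$pool_size <- as.integer(round(params$pool_size))
  params$dense_units <- as.integer(round(params$dense_units))
  params$batch_size <- as.integer(round(params$batch_size))
  n <- nrow(channels[[1]])
  p <- ncol(channels[[1]])
  w <- cnn_init(p, params)
  # Adam state
  mom <- lapply(w[c("Wc", "bc", "W1", "b1", "w2", "b2")], function(x) x * 0)
  vel <- mom
  b1a <- 0.9; b2a <- 0.999; eps <- 1e-8; tstep <- 0
  best_loss <- Inf; stale <- 0
  for (ep in seq_len(params$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = params$batch_size)) {
      rows <- ord[start:min(start + params$batch_size - 1, n)]
      if (length(rows) < 2) next
      bch <- lapply(channels, function(X) X[rows, , drop = FALSE])
      mask <- if (params$dropout > 0)
        matrix(rbinom(length(rows) * ncol(w$W1), 1, 1 - params$dropout),
               length(rows)) / (1 - params$dropout) else NULL
      fw <- cnn_forward(bch, w, params, mask)
      d_out <- 2 * (fw$out - y[rows]) / length(rows)
      g <- cnn_backward(bch, w, params, fw, d_out, mask)
      tstep <- tstep + 1
      for (nm in names(g)) {
        mom[[nm]] <- b1a * mom[[nm]] + (1 - b1a) * g[[nm]]
        vel[[nm]] <- b2a * vel[[nm]] + (1 - b2a) * g[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1a^tstep)
        vhat <- vel[[nm]] / (1 - b2a^tstep)
        w[[nm]] <- w[[nm]] - params$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    loss <- mean((cnn_forward(channels, w, params)$out - y)^2)
    if (loss < best_loss - 1e-6) { best_loss <- loss; stale <- 0 }
    else stale <- stale + 1
    if (stale >= params$patience) break
  }
  structure(list(w = w, params = params), class = "pgs_cnn")
}

cnn_predict <- function(fit, channels) {
  cnn_forward(channels, fit$w, fit$params)$out
}
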