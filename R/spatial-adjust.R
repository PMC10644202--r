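#' Fit a two-dimensional P-spline surface to field phenotypes
#'
#' Penalized tensor-product B-spline surface over the field coordinates with
#' the smoothing parameter chosen by REML (via [mgcv::gam()]); 12 and 13
#' basis functions per axis by default. Missing phenotypes are ignored during
#' fitting but the surface is still evaluated at their positions.
#'
#' The spatial effect is the centered smooth term, so the fitted surface
#' carries no intercept and subtracting it preserves the phenotype mean.
#'
#' @param pheno phenotype table with `row`, `col` and the trait column.
#' @param trait name of the trait column.
#' @param knots basis dimensions per axis, default `c(12, 13)`.
#' @return `spatial_model`: the gam fit, per-tree `surface` values (aligned
#'   with `pheno` rows), smoothing parameter and residual variance.
#' @export
fit_spatial_spline <- function(pheno, trait, knots = c(12, 13)) {
  stopifnot(all(c("row", "col", trait) %in% names(pheno)))
  y <- pheno[[trait]]
  obs <- which(!is.na(y))
  if (length(obs) < 30) stop("need at least 30 non-missing phenotypes")
  r <- pheno$row[obs]; cl <- pheno$col[obs]
  if (sd(r) == 0 || sd(cl) == 0 ||
      abs(cor(r, cl)) > 1 - 1e-10)
    stop("degenerate (collinear) field coordinates")
  dat <- data.frame(y = y[obs], row = r, col = cl)
  k <- pmin(knots, c(length(unique(r)), length(unique(cl))))
  if (sd(dat$y) == 0) {
    # constant response: the smooth is identically zero
    return(structure(list(fit = NULL, trait = trait, knots = k,
                          smoothing = NA_real_,
                          surface = rep(0, nrow(pheno)),
                          residual_variance = 0),
                     class = "spatial_model"))
  }
  fit <- mgcv::gam(y ~ te(row, col, k = k, bs = "ps"),
                   data = dat, method = "REML")
  surface_all <- as.numeric(predict(
    fit, newdata = data.frame(row = pheno$row, col = pheno$col),
    type = "terms")[, 1])
  structure(list(fit = fit, trait = trait, knots = k,
                 smoothing = as.numeric(fit$sp),
                 surface = surface_all,
                 residual_variance = var(residuals(fit))),
            class = "spatial_model")
}

#' Subtract the fitted spatial surface from observed phenotypes
#'
#' @param pheno phenotype table used (row-aligned) in [fit_spatial_spline()].
#' @param model a `spatial_model`.
#' @return `pheno` with the trait column replaced by observed minus spatial
#'   effect (missing stays missing) and the surface in `<trait>_spatial`.
#' @export
adjust_phenotypes <- function(pheno, model) {
  stopifnot(inherits(model, "spatial_model"))
  trait <- model$trait
  if (length(model$surface) != nrow(pheno))
    stop("model was fitted on a table with a different number of rows")
  out <- pheno
  out[[paste0(trait, "_spatial")]] <- model$surface
  out[[trait]] <- pheno[[trait]] - model$surface
  out
}

#' Critical value of the two-tailed Grubbs outlier test
#'
#' Closed form `((n-1)/sqrt(n)) * sqrt(t^2 / (n-2+t^2))` with `t` the
#' `1 - alpha/(2n)` quantile of the t-distribution on `n-2` degrees of
#' freedom.
#'
#' @param n sample size.
#' @param alpha two-tailed significance level.
#' @return critical value for the maximum absolute standardized deviate.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  stopifnot(n >= 3)
  t <- qt(1 - alpha / (2 * n), df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative two-tailed Grubbs outlier removal
#'
#' Repeatedly tests the most extreme standardized deviate against the Grubbs
#' critical value and removes it while the test rejects. Ties on the extreme
#' deviate are broken by the lower index. The significance level is not
#' readjusted across iterations.
#'
#' @param values numeric vector (names, if present, identify the removed
#'   observations; otherwise original indices are used).
#' @param alpha two-tailed level per iteration (default 0.05).
#' @param iterative if FALSE at most one value is removed.
#' @return list with `kept` values and `removed` ids.
#' @export
grubbs_filter <- function(values, alpha = 0.05, iterative = TRUE) {
  if (length(values) < 3) stop("Grubbs test needs at least 3 values")
  ids <- names(values) %||% as.character(seq_along(values))
  removed <- character(0)
  repeat {
    n <- length(values)
    if (n < 3) break
    s <- sd(values)
    if (s == 0) stop("zero standard deviation: Grubbs test undefined")
    dev <- abs(values - mean(values)) / s
    i <- which.max(dev) # which.max returns the first (lowest-index) maximum
    if (dev[i] > grubbs_critical(n, alpha)) {
      removed <- c(removed, ids[i])
      values <- values[-i]
      ids <- ids[-i]
      if (!iterative) break
    } else break
  }
  list(kept = values, removed = removed)
}
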