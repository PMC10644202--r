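#' Default hyperparameter search spaces for the machine-learning methods
#'
#' Declares the tunable spaces sampled during inner cross-validation: a
#' 5-parameter random-forest space, 8-parameter spaces for each of the two
#' gradient-boosting variants (depth-wise `gbdt_a`, xgboost-like, with
#' `max_depth`; leaf-wise `gbdt_b`, lightgbm-like, with `num_leaves`), and a
#' common 7-parameter space for the two convolutional networks. Ranges are a
#' documented reconstruction, not a reproduction of any published space.
#'
#' @return named list of spaces; each space is a named list of parameter
#'   descriptors `list(type, lo, hi, log, default)`.
#' @export
default_search_spaces <- function() {
  par <- function(type, lo, hi, log = FALSE, default = NULL)
    list(type = type, lo = lo, hi = hi, log = log,
         default = default %||% if (log) sqrt(lo * hi) else (lo + hi) / 2)
  cnn <- list(
    n_filters = par("int", 4, 32, log = TRUE, default = 8),
    kernel_size = par("int", 3, 9, default = 5),
    pool_size = par("int", 2, 4, default = 2),
    dense_units = par("int", 8, 64, log = TRUE, default = 16),
    dropout = par("float", 0, 0.5, default = 0.2),
    learning_rate = par("float", 1e-4, 1e-2, log = TRUE, default = 1e-3),
    batch_size = par("int", 16, 64, log = TRUE, default = 32))
  list(
    rf = list(
      n_trees = par("int", 100, 500, default = 200),
      max_depth = par("int", 4, 16, default = 12),
      min_leaf = par("int", 2, 10, default = 5),
      mtry_frac = par("float", 0.1, 1, default = 1 / 3),
      sample_frac = par("float", 0.5, 1, default = 1)),
    gbdt_a = list(
      n_trees = par("int", 50, 400, log = TRUE, default = 100),
      learning_rate = par("float", 0.01, 0.3, log = TRUE, default = 0.1),
      max_depth = par("int", 2, 8, default = 4),
      min_child_weight = par("int", 1, 10, default = 3),
      subsample = par("float", 0.5, 1, default = 0.8),
      colsample_bytree = par("float", 0.3, 1, default = 0.8),
      reg_lambda = par("float", 1e-2, 10, log = TRUE, default = 1),
      gamma = par("float", 0, 1, default = 0)),
    gbdt_b = list(
      n_trees = par("int", 50, 400, log = TRUE, default = 100),
      learning_rate = par("float", 0.01, 0.3, log = TRUE, default = 0.1),
      num_leaves = par("int", 4, 64, log = TRUE, default = 15),
      max_depth = par("int", 3, 12, default = 8),
      min_data_in_leaf = par("int", 2, 20, default = 5),
      bagging_fraction = par("float", 0.5, 1, default = 0.8),
      feature_fraction = par("float", 0.3, 1, default = 0.8),
      reg_lambda = par("float", 1e-2, 10, log = TRUE, default = 1)),
    cnn1d = cnn,
    cnn2d = cnn)
}

# draw one configuration uniformly (log-uniformly where flagged)
sample_params <- function(space) {
  out <- lapply(space, function(p) {
    v <- if (p$log) exp(runif(1, log(p$lo), log(p$hi)))
    else runif(1, p$lo, p$hi)
    if (p$type == "int") v <- as.integer(round(v))
    v
  })
  out
}

default_params <- function(space) lapply(space, `[[`, "default")

#' Deterministic inner cross-validation folds
#'
#' @param n number of training samples.
#' @param k number of folds (default 3).
#' @param seed fold seed.
#' @return integer fold label per sample.
#' @export
make_inner_folds <- function(n, k = 3, seed = 1) {
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

scaler_fit <- function(M) {
  ctr <- colMeans(M)
  scl <- apply(M, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}
scaler_apply <- function(M, s) sweep(sweep(M, 2, s$center), 2, s$scale, "/")

ml_fit_one <- function(method, Xtr, ytr, params, phase_tr = NULL) {
  switch(method,
    rf = fit_random_forest(Xtr, ytr, n_trees = params$n_trees,
                           max_depth = params$max_depth,
                           min_leaf = params$min_leaf,
                           mtry_frac = params$mtry_frac,
                           sample_frac = params$sample_frac),
    gbdt_a = fit_gbdt(Xtr, ytr, variant = "depth",
                      n_trees = params$n_trees,
                      learning_rate = params$learning_rate,
                      max_depth = params$max_depth,
                      min_leaf = params$min_child_weight,
                      subsample = params$subsample,
                      colsample = params$colsample_bytree,
                      reg_lambda = params$reg_lambda, gamma = params$gamma),
    gbdt_b = fit_gbdt(Xtr, ytr, variant = "leaf",
                      n_trees = params$n_trees,
                      learning_rate = params$learning_rate,
                      num_leaves = params$num_leaves,
                      max_depth = params$max_depth,
                      min_leaf = params$min_data_in_leaf,
                      subsample = params$bagging_fraction,
                      colsample = params$feature_fraction,
                      reg_lambda = params$reg_lambda),
    cnn1d = cnn_fit(list(Xtr), ytr, params),
    cnn2d = cnn_fit(list(phase_tr[, , 1], phase_tr[, , 2]), ytr, params),
    stop("unknown method: ", method))
}

ml_predict_one <- function(method, fit, Xte, phase_te = NULL) {
  switch(method,
    rf = predict_rf(fit, Xte),
    gbdt_a = predict_gbdt(fit, Xte),
    gbdt_b = predict_gbdt(fit, Xte),
    cnn1d = cnn_predict(fit, list(Xte)),
    cnn2d = cnn_predict(fit, list(phase_te[, , 1], phase_te[, , 2])))
}

#' Fit a machine-learning predictor with inner-CV hyperparameter search
#'
#' Hyperparameters are drawn from the method's declared space by seeded
#' random search (the tree-structured Parzen sampler the interface emulates
#' is not available here) and scored by k-fold inner cross-validation on the
#' training fold, maximizing the mean Pearson correlation between observed
#' and predicted values; the best configuration is refit on the full
#' training fold.
#'
#' Scaling follows the benchmark conventions: responses and genotype inputs
#' are standardized with training-fold parameters for `cnn1d`; only the
#' response is standardized for `cnn2d` (its phase input stays binary); the
#' tree methods (`rf`, `gbdt_a`, `gbdt_b`) are fitted unscaled.
#'
#' @param method one of `"rf"`, `"gbdt_a"`, `"gbdt_b"`, `"cnn1d"`,
#'   `"cnn2d"`.
#' @param train list with `X` (matrix), `y`, and for `cnn2d` a `phase`
#'   array (samples x SNPs x 2 with 0/1 allele coding).
#' @param validation list with `X` (and `phase` for `cnn2d`).
#' @param space search space for the method (default from
#'   [default_search_spaces()]).
#' @param budget number of sampled configurations (>= 1).
#' @param inner_folds number of inner CV folds (default 3).
#' @param seed master seed for sampling, folds and fits.
#' @param full_set set TRUE when the marker set is the full panel; the
#'   convolutional methods refuse it.
#' @return list with `predictions` (validation scale of `y`),
#'   `best_params`, `inner_r` (best mean inner correlation), `search_log`.
#' @export
fit_predict_ml <- function(method, train, validation, space = NULL,
                           budget = 10, inner_folds = 3, seed = 1,
                           full_set = FALSE) {
  method <- match.arg(method, c("rf", "gbdt_a", "gbdt_b", "cnn1d", "cnn2d"))
  if (full_set && method %in% c("cnn1d", "cnn2d"))
    stop("convolutional methods are not fitted on the full SNP set")
  if (budget < 1) stop("budget must be at least 1")
  space <- space %||% default_search_spaces()[[method]]

  ytr_raw <- train$y
  y_sc <- NULL
  scale_y <- method %in% c("cnn1d", "cnn2d")
  ytr <- if (scale_y) {
    y_sc <- list(center = mean(ytr_raw), scale = max(sd(ytr_raw), 1e-12))
    (ytr_raw - y_sc$center) / y_sc$scale
  } else ytr_raw

  scale_X <- method == "cnn1d"
  x_sc <- if (scale_X) scaler_fit(train$X) else NULL
  Xtr <- if (scale_X) scaler_apply(train$X, x_sc) else train$X
  Xva <- if (scale_X) scaler_apply(validation$X, x_sc) else validation$X

  n <- nrow(Xtr)
  folds <- make_inner_folds(n, inner_folds, substream_seed(seed, "folds"))
  log_rows <- vector("list", budget)
  best <- list(r = -Inf, params = NULL)
  for (t in seq_len(budget)) {
    set.seed(substream_seed(seed, "sample", t))
    params <- if (t == 1) default_params(space) else sample_params(space)
    rs <- vapply(seq_len(inner_folds), function(f) {
      tr <- which(folds != f); te <- which(folds == f)
      set.seed(substream_seed(seed, "inner_fit", t * 100 + f))
      ph_tr <- if (!is.null(train$phase)) train$phase[tr, , , drop = FALSE]
      ph_te <- if (!is.null(train$phase)) train$phase[te, , , drop = FALSE]
      fit <- ml_fit_one(method, Xtr[tr, , drop = FALSE], ytr[tr], params,
                        phase_tr = ph_tr)
      pred <- ml_predict_one(method, fit, Xtr[te, , drop = FALSE],
                             phase_te = ph_te)
      if (sd(pred) < 1e-12 || sd(ytr[te]) < 1e-12) {
        warning("constant predictions in an inner fold; r treated as 0")
        0
      } else cor(ytr[te], pred)
    }, numeric(1))
    r_mean <- mean(rs)
    log_rows[[t]] <- c(trial = t, inner_r = r_mean)
    if (r_mean > best$r) best <- list(r = r_mean, params = params)
  }

  set.seed(substream_seed(seed, "final_fit"))
  fit <- ml_fit_one(method, Xtr, ytr, best$params, phase_tr = train$phase)
  pred <- ml_predict_one(method, fit, Xva, phase_te = validation$phase)
  if (scale_y) pred <- pred * y_sc$scale + y_sc$center
  list(predictions = pred, best_params = best$params, inner_r = best$r,
       search_log = do.call(rbind, log_rows))
}
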