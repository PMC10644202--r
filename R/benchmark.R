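#' Cross-validation plan for the genomic-prediction benchmark
#'
#' Encodes the comparison design: 3:1 training/validation splits (validation
#' size `ceiling(n/4)`), a number of random splits and model-construction
#' replicates, SNP subset sizes selected by within-fold GWAS ranking plus the
#' full panel, and the twelve predictor families. GBLUP is deterministic and
#' gets a single replicate; the convolutional methods are excluded at the
#' full SNP set.
#'
#' @param n_samples number of samples entering the benchmark.
#' @param traits character vector of trait column names.
#' @param methods methods to run (default all twelve).
#' @param n_splits number of training/validation splits (default 10).
#' @param n_model_replicates model-construction replicates (default 10;
#'   forced to 1 for GBLUP).
#' @param subset_sizes character vector from `"48"`, `"96"`, `"192"`,
#'   `"all"`.
#' @param master_seed seed from which all per-cell streams derive.
#' @param ml_budget hyperparameter-search trials per ML fit.
#' @param inner_folds inner CV folds for the ML methods.
#' @param n_pcs principal components used as GWAS covariates.
#' @param bayes_mcmc,rkhs_mcmc chain-length controls for the samplers.
#' @param stratified reserve: family-stratified splits (off by default,
#'   mirroring unstratified random splits).
#' @return a `cv_plan`.
#' @export
cv_plan <- function(n_samples, traits,
                    methods = c("gblup", "bayesA", "bayesB", "bayesC",
                                "brr", "bl", "rkhs", "rf", "gbdt_a",
                                "gbdt_b", "cnn1d", "cnn2d"),
                    n_splits = 10, n_model_replicates = 10,
                    subset_sizes = c("48", "96", "192", "all"),
                    master_seed = 1, ml_budget = 10, inner_folds = 3,
                    n_pcs = 4,
                    bayes_mcmc = list(n_iter = 3000, burn_in = 1000,
                                      thin = 5),
                    rkhs_mcmc = list(n_iter = 3000, burn_in = 1000,
                                     thin = 5),
                    stratified = FALSE) {
  if (n_samples < 8) stop("need at least 8 samples for 3:1 splits")
  subset_sizes <- as.character(subset_sizes)
  bad <- setdiff(subset_sizes, c("48", "96", "192", "all"))
  if (length(bad)) stop("unknown subset sizes: ", paste(bad, collapse = ", "))
  structure(list(n_samples = n_samples, traits = traits, methods = methods,
                 n_splits = n_splits,
                 n_model_replicates = n_model_replicates,
                 subset_sizes = subset_sizes, master_seed = master_seed,
                 ml_budget = ml_budget, inner_folds = inner_folds,
                 n_pcs = n_pcs, bayes_mcmc = bayes_mcmc,
                 rkhs_mcmc = rkhs_mcmc, stratified = stratified,
                 validation_size = ceiling(n_samples / 4)),
            class = "cv_plan")
}

bayes_family <- c(bayesA = "BayesA", bayesB = "BayesB", bayesC = "BayesC",
                  brr = "BRR", bl = "BL")

method_replicates <- function(method, plan) {
  if (method == "gblup") 1L else plan$n_model_replicates
}

method_runs_subset <- function(method, subset) {
  !(subset == "all" && method %in% c("cnn1d", "cnn2d"))
}

#' Seeded 3:1 training/validation splits
#'
#' Independent random partitions with validation size `ceiling(n/4)`;
#' regenerates until all splits are distinct.
#'
#' @param n number of samples.
#' @param plan a [cv_plan()] (uses `n_splits`, `master_seed`).
#' @return list of `list(train, validation)` index sets.
#' @export
make_splits <- function(n, plan) {
  if (n < 8) stop("need at least 8 samples")
  if (n < 4) stop("too few samples to split 3:1")
  v <- ceiling(n / 4)
  splits <- list()
  seen <- character(0)
  attempt <- 0L
  while (length(splits) < plan$n_splits) {
    attempt <- attempt + 1L
    if (attempt > 100 * plan$n_splits)
      stop("could not generate distinct splits")
    set.seed(substream_seed(plan$master_seed, "split", attempt))
    val <- sort(sample.int(n, v))
    key <- paste(val, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    splits[[length(splits) + 1]] <- list(train = setdiff(seq_len(n), val),
                                         validation = val)
  }
  splits
}

#' Predictive ability: Pearson correlation of observed and predicted values
#'
#' Constant predictions yield no correlation; such cells are flagged
#' degenerate and carry no value.
#'
#' @param observed,predicted equal-length numeric vectors (length >= 3).
#' @return list with `r` (NA when degenerate) and `degenerate`.
#' @export
predictive_ability <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("need at least 3 pairs")
  if (sd(predicted) < 1e-12 || sd(observed) < 1e-12)
    return(list(r = NA_real_, degenerate = TRUE))
  list(r = cor(observed, predicted), degenerate = FALSE)
}

#' Closed-form count of model fits implied by a plan
#'
#' Honors the GBLUP single-replicate rule and the exclusion of the
#' convolutional methods at the full SNP set. Under the headline design
#' (12 methods, 10 splits x 10 replicates, 4 subset sizes, 2 traits) this
#' gives 8480.
#'
#' @param plan a [cv_plan()].
#' @return total number of model fits.
#' @export
count_models <- function(plan) {
  stopifnot(inherits(plan, "cv_plan"))
  per_trait_split <- sum(vapply(plan$methods, function(m) {
    sum(vapply(plan$subset_sizes, function(s) {
      if (method_runs_subset(m, s)) as.numeric(method_replicates(m, plan))
      else 0
    }, numeric(1)))
  }, numeric(1)))
  as.integer(length(plan$traits) * plan$n_splits * per_trait_split)
}

#' One-sample test of deviation of a benchmark cell from zero
#'
#' Two-sided Wilcoxon signed-rank test of the replicate predictive
#' abilities against zero.
#'
#' @param values replicate predictive abilities (>= 6 non-missing).
#' @return p-value.
#' @export
deviation_from_zero <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 6) stop("need at least 6 replicate values")
  if (length(unique(values)) == 1) stop("all replicate values identical")
  suppressWarnings(wilcox.test(values, mu = 0, exact = FALSE)$p.value)
}

#' Run the full cross-validated genomic-prediction benchmark
#'
#' For every trait and split: a mixed-model GWAS is run on the training fold
#' only, SNP subsets are taken as the lowest-p markers, and every
#' method x subset x replicate is fitted on the training fold and scored on
#' the validation fold by predictive ability. Scaling follows the
#' training-only convention (standardization parameters are estimated on the
#' training fold and applied to the validation fold); genotype scaling is
#' omitted for the tree methods, GBLUP and the phase input of `cnn2d`.
#' Stage errors are recorded per cell and the run continues.
#'
#' @param data list with `genotypes` (a complete [geno_matrix()], optionally
#'   phased) and `phenotypes` (data.frame with `tree_id` and the adjusted
#'   trait columns, covering all genotyped samples).
#' @param plan a [cv_plan()].
#' @return `benchmark_result`: long results table, per-cell medians with
#'   zero-deviation p-values, and the plan.
#' @export
run_benchmark <- function(data, plan) {
  stopifnot(inherits(plan, "cv_plan"), inherits(data$genotypes, "geno_matrix"))
  g <- data$genotypes
  if (anyNA(g$codes)) stop("impute genotypes before benchmarking")
  pheno <- data$phenotypes
  idx <- match(rownames(g$codes), pheno$tree_id)
  if (anyNA(idx)) stop("phenotype table does not cover all genotyped samples")

  rows <- list()
  for (trait in plan$traits) {
    y_all <- pheno[[trait]][idx]
    use <- which(!is.na(y_all))
    y <- y_all[use]
    X <- g$codes[use, , drop = FALSE]
    phase <- if (!is.null(g$phase)) g$phase[use, , , drop = FALSE]
    n <- length(use)
    plan_t <- plan
    plan_t$master_seed <- substream_seed(plan$master_seed, trait)
    splits <- make_splits(n, plan_t)

    for (s in seq_along(splits)) {
      tr <- splits[[s]]$train
      va <- splits[[s]]$validation
      Xtr <- X[tr, , drop = FALSE]

      subset_idx <- list()
      need_scan <- any(plan$subset_sizes != "all")
      scan <- NULL
      if (need_scan) {
        scan <- tryCatch({
          kin <- suppressWarnings(vanraden_a_matrix(Xtr))
          mixed_scan(y[tr], Xtr, kin,
                     n_pcs = min(plan$n_pcs, length(tr) - 2))
        }, error = function(e) e)
      }
      for (ss in plan$subset_sizes) {
        if (ss == "all") {
          subset_idx[[ss]] <- seq_len(ncol(X))
        } else if (inherits(scan, "error")) {
          subset_idx[[ss]] <- scan
        } else {
          subset_idx[[ss]] <- tryCatch(select_top_k(scan, as.integer(ss)),
                                       error = function(e) e)
        }
      }

      for (method in plan$methods) {
        for (ss in plan$subset_sizes) {
          if (!method_runs_subset(method, ss)) next
          sel <- subset_idx[[ss]]
          for (rep_i in seq_len(method_replicates(method, plan))) {
            cell_seed <- substream_seed(
              plan$master_seed,
              paste(trait, method, ss, sep = "_"), s * 1000 + rep_i)
            res <- if (inherits(sel, "error")) {
              list(r = NA_real_, degenerate = FALSE,
                   error = conditionMessage(sel))
            } else {
              tryCatch({
                pred <- fit_benchmark_cell(
                  method, y, X, phase, tr, va, sel, plan, cell_seed,
                  full_set = (ss == "all"))
                pa <- predictive_ability(y[va], pred)
                list(r = pa$r, degenerate = pa$degenerate, error = NA)
              }, error = function(e)
                list(r = NA_real_, degenerate = FALSE,
                     error = conditionMessage(e)))
            }
            rows[[length(rows) + 1]] <- data.frame(
              trait = trait, method = method, subset = ss, split = s,
              replicate = rep_i, ability = res$r,
              degenerate = res$degenerate,
              error = as.character(res$error), stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  medians <- aggregate_benchmark(results)
  structure(list(results = results, medians = medians, plan = plan),
            class = "benchmark_result")
}

# one model fit + validation prediction for a benchmark cell
fit_benchmark_cell <- function(method, y, X, phase, tr, va, sel, plan,
                               seed, full_set) {
  Xs <- X[, sel, drop = FALSE]
  ytr <- y[tr]
  if (method %in% names(bayes_family)) {
    y_sc <- list(center = mean(ytr), scale = max(sd(ytr), 1e-12))
    x_sc <- scaler_fit(Xs[tr, , drop = FALSE])
    Xz <- scaler_apply(Xs, x_sc)
    spec <- bayes_spec(bayes_family[[method]],
                       n_iter = plan$bayes_mcmc$n_iter,
                       burn_in = plan$bayes_mcmc$burn_in,
                       thin = plan$bayes_mcmc$thin, seed = seed)
    fit <- suppressWarnings(
      fit_bayes((ytr - y_sc$center) / y_sc$scale,
                Xz[tr, , drop = FALSE], spec))
    predict(fit, Xz[va, , drop = FALSE]) * y_sc$scale + y_sc$center
  } else if (method == "gblup") {
    all_idx <- c(tr, va)
    K <- suppressWarnings(vanraden_a_matrix(Xs[all_idx, , drop = FALSE]))
    fit <- fit_gblup(ytr, K, seq_along(tr),
                     length(tr) + seq_along(va))
    fit$predictions
  } else if (method == "rkhs") {
    y_sc <- list(center = mean(ytr), scale = max(sd(ytr), 1e-12))
    x_sc <- scaler_fit(Xs[tr, , drop = FALSE])
    Xz <- scaler_apply(Xs, x_sc)
    all_idx <- c(tr, va)
    K <- gaussian_kernel(Xz[all_idx, , drop = FALSE], bandwidth = 1)
    mc <- plan$rkhs_mcmc; mc$seed <- seed
    fit <- fit_rkhs((ytr - y_sc$center) / y_sc$scale, K, seq_along(tr),
                    length(tr) + seq_along(va), mcmc = mc)
    fit$predictions * y_sc$scale + y_sc$center
  } else {
    train <- list(X = Xs[tr, , drop = FALSE], y = ytr,
                  phase = if (!is.null(phase)) phase[tr, sel, , drop = FALSE])
    validation <- list(X = Xs[va, , drop = FALSE],
                       phase = if (!is.null(phase))
                         phase[va, sel, , drop = FALSE])
    fit <- suppressWarnings(
      fit_predict_ml(method, train, validation, budget = plan$ml_budget,
                     inner_folds = plan$inner_folds, seed = seed,
                     full_set = full_set))
    fit$predictions
  }
}

# per-cell medians over non-missing replicate values + zero-deviation test
aggregate_benchmark <- function(results) {
  cells <- unique(results[, c("trait", "method", "subset")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- results[results$trait == cells$trait[i] &
                     results$method == cells$method[i] &
                     results$subset == cells$subset[i], ]
    vals <- sub$ability[!is.na(sub$ability)]
    p <- tryCatch(deviation_from_zero(vals), error = function(e) NA_real_)
    data.frame(cells[i, , drop = FALSE],
               median_ability = if (length(vals)) median(vals) else NA_real_,
               n_values = length(vals),
               n_degenerate = sum(sub$degenerate),
               p_zero = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: %d fits, %d cells\n", nrow(x$results),
              nrow(x$medians)))
  print(utils::head(x$medians, 20))
  invisible(x)
}
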