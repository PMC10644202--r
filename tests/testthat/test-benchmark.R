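test_that("splits are 3:1 partitions with the documented validation size", {
  plan <- cv_plan(281, "D7", n_splits = 10)
  expect_equal(plan$validation_size, 71)
  s <- make_splits(281, plan)
  expect_equal(length(s), 10)
  for (sp in s) {
    expect_equal(length(sp$validation), 71)
    expect_equal(sort(c(sp$train, sp$validation)), 1:281)
    expect_equal(length(intersect(sp$train, sp$validation)), 0)
  }
  # all splits distinct
  keys <- sapply(s, function(x) paste(x$validation, collapse = ","))
  expect_equal(anyDuplicated(keys), 0)
  # minimal case: 8 samples -> 6 train / 2 validation
  s8 <- make_splits(8, cv_plan(8, "D7", n_splits = 2))
  expect_equal(length(s8[[1]]$validation), 2)
  expect_error(make_splits(4, cv_plan(8, "D7")), "at least 8")
  expect_error(cv_plan(4, "D7"), "at least 8")
})

test_that("predictive ability is the Pearson r with a degenerate flag", {
  y <- rnorm(20)
  expect_equal(predictive_ability(y, y)$r, 1)
  expect_equal(predictive_ability(y, -y)$r, -1)
  d <- predictive_ability(y, rep(2, 20))
  expect_true(d$degenerate)
  expect_true(is.na(d$r))
  expect_error(predictive_ability(y, y[-1]), "length mismatch")
  expect_error(predictive_ability(y[1:2], y[1:2]), "at least 3")
})

test_that("count_models reproduces the benchmark design arithmetic", {
  # headline design: 12 methods, 10 x 10, 4 subset sizes, 2 traits,
  # GBLUP single-replicate and CNN full-set exclusion -> 8480 fits
  plan <- cv_plan(281, c("D7", "H7"), n_splits = 10, n_model_replicates = 10)
  expect_equal(count_models(plan), 8480)
  # single-cell plan
  p1 <- cv_plan(100, "D7", methods = "brr", n_splits = 1,
                n_model_replicates = 1, subset_sizes = "48")
  expect_equal(count_models(p1), 1)
  # GBLUP-only: replicate rule forces 1 x 10 x 4 x 2 = 80
  pg <- cv_plan(281, c("D7", "H7"), methods = "gblup", n_splits = 10,
                n_model_replicates = 10)
  expect_equal(count_models(pg), 80)
})

test_that("the zero-deviation test behaves at both extremes", {
  expect_lt(deviation_from_zero(rep(c(0.3, 0.31, 0.29), 4)), 0.01)
  set.seed(1)
  p_null <- replicate(50, deviation_from_zero(rnorm(12, 0, 0.1)))
  expect_gt(median(p_null), 0.05)
  expect_error(deviation_from_zero(c(0.1, 0.2)), "at least 6")
  expect_error(deviation_from_zero(rep(0.2, 8)), "identical")
})

test_that("run_benchmark produces exactly the planned cells, reproducibly", {
  cfg <- tiny_config(seed = 81, n_mothers = 20,
                     progeny_per_family_per_block = 2, n_blocks = 4,
                     n_scaffolds = 12, snps_per_scaffold = 10,
                     spatial_variance_fraction = 0,
                     phenotype_missing_rate = 0)
  trial <- simulate_trial(cfg, trait_specs = list(
    T1 = list(h2_additive = 0.4, h2_epistatic = 0,
              bimodal_major_qtl = FALSE)))
  dat <- list(genotypes = trial$genotypes, phenotypes = trial$phenotypes)
  plan <- cv_plan(nrow(trial$genotypes$codes), "T1",
                  methods = c("gblup", "brr", "bayesB", "rkhs", "rf",
                              "gbdt_b", "cnn1d"),
                  n_splits = 2, n_model_replicates = 2,
                  subset_sizes = c("48", "all"), master_seed = 5,
                  ml_budget = 1,
                  bayes_mcmc = list(n_iter = 800, burn_in = 200, thin = 5),
                  rkhs_mcmc = list(n_iter = 800, burn_in = 200, thin = 5))
  bm <- suppressWarnings(run_benchmark(dat, plan))
  expect_equal(nrow(bm$results), count_models(plan))
  # cnn never fitted on the full set
  expect_equal(sum(bm$results$method == "cnn1d" & bm$results$subset == "all"), 0)
  # gblup deterministic: one replicate per split
  expect_equal(sum(bm$results$method == "gblup"), 2 * 2)
  ok <- !is.na(bm$results$ability)
  expect_true(all(abs(bm$results$ability[ok]) <= 1))
  # no unexpected per-cell errors on clean input
  expect_true(all(is.na(bm$results$error) | bm$results$error == "NA"))
  # an additive trait is predictable: gblup at "all" clearly positive
  med <- bm$medians
  expect_gt(med$median_ability[med$method == "gblup" & med$subset == "all"], 0.1)
  # reproducibility from the master seed
  bm2 <- suppressWarnings(run_benchmark(dat, plan))
  expect_equal(bm$results$ability, bm2$results$ability)
})

test_that("shuffled phenotypes give near-zero medians", {
  cfg <- tiny_config(seed = 91, n_mothers = 20,
                     progeny_per_family_per_block = 2, n_blocks = 4,
                     n_scaffolds = 12, snps_per_scaffold = 10,
                     spatial_variance_fraction = 0, phenotype_missing_rate = 0)
  trial <- simulate_trial(cfg, trait_specs = list(
    T1 = list(h2_additive = 0.4, h2_epistatic = 0,
              bimodal_major_qtl = FALSE)))
  set.seed(3)
  trial$phenotypes$T1 <- sample(trial$phenotypes$T1)
  plan <- cv_plan(nrow(trial$genotypes$codes), "T1",
                  methods = c("gblup", "brr"), n_splits = 3,
                  n_model_replicates = 2, subset_sizes = "all",
                  master_seed = 9,
                  bayes_mcmc = list(n_iter = 800, burn_in = 200, thin = 5))
  bm <- suppressWarnings(run_benchmark(
    list(genotypes = trial$genotypes, phenotypes = trial$phenotypes), plan))
  expect_true(all(abs(bm$medians$median_ability) < 0.15, na.rm = TRUE))
})
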