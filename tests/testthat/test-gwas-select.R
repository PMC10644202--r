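test_that("scan with identity kinship reproduces plain linear regression", {
  set.seed(1)
  X <- random_geno(80, 60, seed = 1)
  y <- rnorm(80) + X[, 5] * 0.8
  scan <- mixed_scan(y, X, diag(80), n_pcs = 0)
  p_lm <- sapply(seq_len(60), function(j)
    summary(lm(y ~ X[, j]))$coefficients[2, 4])
  expect_lt(max(abs(scan$p - p_lm)), 1e-6)
  expect_equal(which.min(scan$p), 5)
})

test_that("a planted large-effect QTL attains the smallest p of the scan", {
  cfg <- tiny_config(seed = 51, n_mothers = 30,
                     progeny_per_family_per_block = 2, n_blocks = 4,
                     phenotype_missing_rate = 0)
  prog <- simulate_progeny(simulate_founder_haplotypes(cfg), cfg)
  X <- prog$genotypes$codes
  set.seed(2)
  qtl <- 37
  y <- X[, qtl] * 1.5 + rnorm(nrow(X))
  K <- suppressWarnings(vanraden_a_matrix(X))
  scan <- mixed_scan(y, prog$genotypes, K, n_pcs = 4)
  expect_equal(which.min(scan$p), qtl)
  expect_gt(scan$lod[qtl], 3)
  expect_true(scan$above_threshold[qtl])
  # LOD and -log10(p) rank-concordant
  ok <- !is.na(scan$p)
  expect_gt(cor(scan$lod[ok], -log10(scan$p[ok]), method = "spearman"), 0.99)
  # monomorphic SNP skipped with NA
  X2 <- X; X2[, 3] <- -1
  scan2 <- suppressWarnings(
    mixed_scan(y, X2, suppressWarnings(vanraden_a_matrix(X2)), n_pcs = 0))
  expect_true(is.na(scan2$p[3]))
})

test_that("kinship and PCs deflate structure-driven inflation", {
  tp <- two_pool_geno(60, 250, seed = 3)
  set.seed(4)
  # trait confounded with the pool split
  y <- 0.8 * (tp$pool - 1.5) + rnorm(nrow(tp$X), 0, 1)
  naive <- mixed_scan(y, tp$X, diag(nrow(tp$X)), n_pcs = 0)
  corrected <- mixed_scan(y, tp$X, vanraden_a_matrix(tp$X), n_pcs = 4)
  li_naive <- inflation_factor(naive$p)
  li_corr <- inflation_factor(corrected$p)
  expect_lt(abs(li_corr - 1), abs(li_naive - 1))
})

test_that("BH adjustment matches hand computation and brute force", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  # brute force: q_(k) = min over j >= k of p_(j) * m / j, capped at 1
  brute <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    qs <- sapply(seq_len(m), function(k) min(pmin(ps[k:m] * m / (k:m), 1)))
    out <- numeric(m)
    out[o] <- qs
    out
  }
  set.seed(5)
  for (rep in 1:5) {
    p <- runif(sample(5:40, 1))
    expect_equal(fdr_adjust(p), brute(p), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("top-k selection is deterministic with genome-order tie-breaks", {
  res <- data.frame(
    id = paste0("s", 1:6),
    scaffold = c("a", "a", "b", "b", "c", "c"),
    pos = c(10, 20, 5, 30, 1, 2),
    p = c(0.5, 0.01, 0.01, 0.2, NA, 0.9))
  class(res) <- c("gwas_result", "data.frame")
  # k = all defined -> identity of defined set
  expect_equal(select_top_k(res, 5), c(1, 2, 3, 4, 6))
  # tie at rank 1 between rows 2 (a:20) and 3 (b:5): scaffold order wins
  expect_equal(select_top_k(res, 1), 2)
  expect_equal(select_top_k(res, 2), c(2, 3))
  expect_error(select_top_k(res, 6), "exceeds")
})

test_that("top-48 sets are enriched for markers linked to planted QTL", {
  cfg <- tiny_config(seed = 61, n_mothers = 40,
                     progeny_per_family_per_block = 2, n_blocks = 4,
                     n_scaffolds = 30, snps_per_scaffold = 15,
                     phenotype_missing_rate = 0)
  prog <- simulate_progeny(simulate_founder_haplotypes(cfg), cfg)
  X <- prog$genotypes$codes
  set.seed(6)
  qtl <- sort(sample(ncol(X), 20))
  y <- drop(scale(X[, qtl] %*% rnorm(20))) * sqrt(0.6) +
    rnorm(nrow(X), 0, sqrt(0.4))
  scan <- mixed_scan(y, prog$genotypes,
                     suppressWarnings(vanraden_a_matrix(X)), n_pcs = 4)
  top <- select_top_k(scan, 48)
  hits <- length(intersect(top, qtl))
  p_hyper <- phyper(hits - 1, 20, ncol(X) - 20, 48, lower.tail = FALSE)
  expect_lt(p_hyper, 0.01)
})

test_that("subset overlap and polymorphism checks behave on edge cases", {
  expect_equal(subset_overlap(list(1:48, 1:48)), 100)
  expect_equal(subset_overlap(list(1:10, 11:20)), 0)
  expect_error(subset_overlap(list(1:5)), "2 folds")
  expect_error(subset_overlap(list(1:5, 1:6)), "differ")
  # overlap grows with effect size on a common additive trait
  cfg <- tiny_config(seed = 71, n_mothers = 40,
                     progeny_per_family_per_block = 2, n_blocks = 4,
                     phenotype_missing_rate = 0)
  prog <- simulate_progeny(simulate_founder_haplotypes(cfg), cfg)
  X <- prog$genotypes$codes
  qtl <- sort(sample(ncol(X), 10))
  shares <- sapply(c(0.2, 3), function(ef) {
    set.seed(7)
    g <- drop(X[, qtl] %*% rep(ef, 10))
    sets <- lapply(1:3, function(f) {
      set.seed(100 + f)
      tr <- sample(nrow(X), 200)
      y <- g[tr] + rnorm(200)
      s <- mixed_scan(y, X[tr, ],
                      suppressWarnings(vanraden_a_matrix(X[tr, ])), n_pcs = 2)
      select_top_k(s, 24)
    })
    subset_overlap(sets)
  })
  expect_gt(shares[2], shares[1])

  X_tr <- X[1:50, ]
  mono <- which(apply(X_tr, 2, function(x) length(unique(x))) == 1)[1]
  poly <- which(apply(X_tr, 2, function(x) length(unique(x))) > 1)[1:3]
  if (!is.na(mono)) {
    chk <- check_polymorphism(X_tr, c(poly, mono))
    expect_false(chk$pass)
    expect_true(mono %in% chk$monomorphic)
  }
  expect_true(check_polymorphism(X_tr, poly)$pass)
  expect_true(check_polymorphism(X_tr, integer(0))$pass)
})
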