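test_that("read_vcf applies the -1/0/1 coding and drops non-biallelic sites", {
  path <- write_tiny_vcf(c(
    vcf_header(c("s1", "s2", "s3")),
    "sc1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "sc1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0\t1/1",
    "sc1\t300\t.\tG\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2",
    "sc2\t150\t.\tT\tTA\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1"))
  expect_message(g <- read_vcf(path), "dropped 2")
  expect_equal(ncol(g$codes), 2)
  expect_equal(unname(g$codes[, "sc1_100"]), c(-1, 0, 1))
  expect_equal(unname(g$codes[, "sc1_200"]), c(NA, -1, 1))
  expect_null(g$phase) # mixed phase status -> unphased
})

test_that("read_vcf retains phase bars when fully phased", {
  path <- write_tiny_vcf(c(
    vcf_header(c("s1", "s2")),
    "sc1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|0",
    "sc1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|0"))
  g <- read_vcf(path)
  expect_equal(g$phase[, 1, 1], c(0L, 1L), ignore_attr = TRUE)
  expect_equal(g$phase[, 1, 2], c(1L, 0L), ignore_attr = TRUE)
  expect_equal(unname(g$codes[, 1]), c(0, 0)) # both het, opposite phase
})

test_that("the exact Hardy-Weinberg test matches brute-force enumeration", {
  # independent oracle: enumerate heterozygote configurations with choose()
  oracle <- function(naa, nab, nbb) {
    n <- naa + nab + nbb; na <- 2 * naa + nab
    hets <- seq(nab %% 2, min(na, 2 * n - na), by = 2)
    prob <- sapply(hets, function(h) {
      choose(n, (na - h) / 2) * choose(n - (na - h) / 2, h) *
        2^h / choose(2 * n, na)
    })
    prob <- prob / sum(prob)
    sum(prob[prob <= prob[hets == nab] + 1e-12])
  }
  set.seed(4)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    na <- sample(1:(2 * n - 1), 1)
    hset <- seq(na %% 2, min(na, 2 * n - na), by = 2)
    nab <- hset[sample.int(length(hset), 1)]
    naa <- (na - nab) / 2
    nbb <- n - naa - nab
    expect_equal(hwe_exact_p(naa, nab, nbb), oracle(naa, nab, nbb),
                 tolerance = 1e-10)
  }
  # (AA=5, Aa=0, aa=5): only the zero-heterozygote table is as extreme, so
  # p equals its exact conditional probability 252/choose(20, 10)
  expect_equal(hwe_exact_p(5, 0, 5), 252 / choose(20, 10), tolerance = 1e-10)
  expect_lt(hwe_exact_p(5, 0, 5), 0.0014)
  # perfect HWE proportions are retained at any threshold
  expect_gt(hwe_exact_p(25, 50, 25), 0.05)
})

test_that("filter_sites applies call-rate, MAF and HWE rules idempotently", {
  set.seed(2)
  X <- random_geno(40, 30, seed = 2)
  # plant violations: low MAF, missingness, HWE failure
  X[, 1] <- c(1, rep(-1, 39))              # MAF 0.0125 < 0.05
  X[1:10, 2] <- NA                          # call rate 0.75 < 0.95
  X[, 3] <- rep(c(-1, 1), each = 20)        # no hets: HWE p tiny
  g <- as_geno(X, n_scaffolds = 3)
  f <- filter_sites(g, max_missing = 0.95, maf_min = 0.05, hwe_p_min = 0.001)
  expect_false(any(c("sc01_500", "sc01_1000", "sc01_1500") %in% f$loci$id))
  # idempotence
  f2 <- filter_sites(f, 0.95, 0.05, 0.001)
  expect_identical(f$codes, f2$codes)
  # all loci removed warns rather than errors
  gg <- as_geno(matrix(rep(c(1, rep(-1, 39)), 2), 40, 2), 1)
  expect_warning(filter_sites(gg, maf_min = 0.4), "every locus")
})

test_that("sample filtering, solitary-SNP removal and thinning follow their rules", {
  X <- random_geno(10, 6, seed = 3)
  X[1, 1:5] <- NA # sample 1: 5/6 missing
  g <- as_geno(X, n_scaffolds = 2)
  f <- filter_samples(g, max_sample_missing = 0.65)
  expect_equal(nrow(f$codes), 9)
  expect_false("s001" %in% rownames(f$codes))
  # fully-called samples kept
  expect_true(all(rownames(X)[-1] %in% rownames(f$codes)))

  # solitary SNPs
  X2 <- random_geno(10, 3, seed = 4)
  g2 <- geno_matrix(X2, data.frame(scaffold = c("a", "a", "b"),
                                   pos = c(100, 900, 50)))
  s <- remove_solitary_snps(g2)
  expect_equal(unique(s$loci$scaffold), "a")
  expect_equal(ncol(s$codes), 2)

  # greedy thinning trace: 100, 900, 1200 -> keep 100 and 1200
  X3 <- random_geno(10, 3, seed = 5)
  g3 <- geno_matrix(X3, data.frame(scaffold = "a", pos = c(100, 900, 1200)))
  t3 <- thin_by_distance(g3, 1000)
  expect_equal(t3$loci$pos, c(100, 1200))
  # per-scaffold rule: close positions on different scaffolds both kept
  g4 <- geno_matrix(random_geno(10, 2, seed = 6),
                    data.frame(scaffold = c("a", "b"), pos = c(100, 150)))
  expect_equal(ncol(thin_by_distance(g4, 1000)$codes), 2)
  # invariant: no within-scaffold pair closer than min_bp
  cfg <- tiny_config(seed = 31)
  panel <- simulate_founder_haplotypes(cfg)
  prog <- simulate_progeny(panel, cfg)
  th <- thin_by_distance(prog$genotypes, 1000)
  for (sc in unique(th$loci$scaffold)) {
    pos <- th$loci$pos[th$loci$scaffold == sc]
    if (length(pos) > 1) expect_true(all(diff(pos) >= 1000))
  }
})

test_that("imputation fills by mean or mode and refuses all-missing loci", {
  X <- matrix(c(-1, 1, NA, 1, 1, NA, NA, NA, NA), 3, 3)
  g <- as_geno(X)
  m1 <- impute_missing(subset_geno(g, loci = 1:2), "mean")
  expect_equal(unname(m1$codes[3, 1]), 0) # mean of -1 and 1
  m2 <- impute_missing(subset_geno(g, loci = 1:2), "mode")
  expect_equal(unname(m2$codes[3, 2]), 1)
  expect_error(impute_missing(g, "mean"), "all genotypes missing")
  # no missing input -> identity
  Xc <- random_geno(10, 4, seed = 7)
  expect_identical(impute_missing(as_geno(Xc), "mean")$codes, as_geno(Xc)$codes)
})

test_that("PCA is a centered SVD that preserves distances and separates structure", {
  X <- random_geno(30, 50, seed = 8)
  X <- rbind(X, X[1, , drop = FALSE]) # duplicated individual
  rownames(X) <- NULL
  g <- as_geno(X)
  p <- genotype_pca(g)
  expect_equal(p$coordinates[1, ], p$coordinates[31, ])
  expect_true(all(diff(p$var_explained_pct) <= 1e-8))
  expect_lte(sum(p$var_explained_pct), 100 + 1e-8)
  # full-rank coordinates reproduce pairwise distances of centered data
  d_pc <- dist(p$coordinates)
  d_raw <- dist(scale(X, scale = FALSE))
  expect_equal(as.numeric(d_pc), as.numeric(d_raw), tolerance = 1e-8)
  # two diverged pools are separated on PC1 (silhouette > 0.5)
  tp <- two_pool_geno(40, 150, seed = 9)
  pc <- genotype_pca(as_geno(tp$X))
  pc1 <- pc$coordinates[, 1]
  sil <- sapply(seq_along(pc1), function(i) {
    own <- mean(abs(pc1[i] - pc1[tp$pool == tp$pool[i]][-i]))
    oth <- mean(abs(pc1[i] - pc1[tp$pool != tp$pool[i]]))
    (oth - own) / max(own, oth)
  })
  expect_gt(mean(sil), 0.5)
  expect_error(genotype_pca(as_geno(X[1, , drop = FALSE])), "2 samples")
})

test_that("pairwise r2 equals brute-force correlation and nulls average ~1/(n-1)", {
  X <- random_geno(50, 20, seed = 10)
  g <- as_geno(X, n_scaffolds = 2)
  ld <- pairwise_ld(g)
  # oracle identity on a handful of pairs
  for (k in sample(nrow(ld), 10)) {
    sc <- ld$scaffold[k]
    idx <- which(g$loci$scaffold == sc)
    pos <- g$loci$pos[idx]
    cand <- which(abs(outer(pos, pos, "-")) == ld$dist[k] & upper.tri(diag(length(pos))),
                  arr.ind = TRUE)
    r2s <- cor(g$codes[, idx[cand[, 1]]], g$codes[, idx[cand[, 2]]])^2
    expect_true(any(abs(diag(as.matrix(r2s)) - ld$r2[k]) < 1e-12))
  }
  # duplicated loci give r2 = 1
  Xd <- cbind(X[, 1], X[, 1])
  colnames(Xd) <- c("a", "b")
  gd <- geno_matrix(Xd, data.frame(scaffold = "s", pos = c(1, 100)))
  expect_equal(pairwise_ld(gd)$r2, 1)
  # monomorphic loci are skipped with a message
  Xm <- cbind(X[, 1:2], rep(1, 50))
  gm <- geno_matrix(Xm, data.frame(scaffold = "s", pos = c(1, 50, 99)))
  expect_message(ldm <- pairwise_ld(gm), "monomorphic")
  expect_equal(nrow(ldm), 1)
  # independent loci: mean r2 ~ 1/(n-1)
  n <- 300
  Xn <- random_geno(n, 150, p = rep(0.3, 150), seed = 11)
  gn <- as_geno(Xn, n_scaffolds = 1)
  ldn <- pairwise_ld(gn)
  expect_equal(mean(ldn$r2), 1 / (n - 1), tolerance = 0.4)
})

test_that("ld_decay finds the analytic crossing and flags non-crossing curves", {
  delta <- 800
  ld <- data.frame(scaffold = "s", dist = seq(10, 8000, by = 10))
  ld$r2 <- exp(-ld$dist / delta)
  dec <- ld_decay(ld)
  expect_equal(dec$decay_bp, delta * log(10), tolerance = 0.02)
  # curve entirely above the cut -> absent value
  ld2 <- ld; ld2$r2 <- 0.5 + 0.4 * exp(-ld2$dist / delta)
  expect_true(is.na(ld_decay(ld2)$decay_bp))
  expect_error(ld_decay(ld[1:10, ]), "20")
})

test_that("genome size and coverage arithmetic matches the worked example", {
  gc <- estimate_genome_coverage(0.372, 2236, 8709)
  expect_equal(gc$genome_bp, 363816000)
  expect_equal(round(gc$coverage_pct, 2), 5.35)
  expect_equal(estimate_genome_coverage(1, 1, 1)$genome_bp, 0.978e9)
})
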