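test_that("config validation rejects impossible designs", {
  expect_error(sim_config(snps_per_scaffold = 1), "snps_per_scaffold")
  expect_error(sim_config(maf_min = 0.6), "maf_min")
  expect_error(sim_config(h2_additive = 0.6, h2_epistatic = 0.3,
                          spatial_variance_fraction = 0.2), "variance fractions")
  expect_error(sim_config(n_blocks = 0), "positive")
  cfg <- sim_config()
  expect_equal(cfg$n_trees, 94 * 5 * 8)
})

test_that("founder haplotypes respect the MAF floor, ordering and LD decay", {
  cfg <- tiny_config(seed = 3, maf_min = 0.05)
  panel <- simulate_founder_haplotypes(cfg)
  freq <- colMeans(panel$alleles)
  expect_true(all(pmin(freq, 1 - freq) >= 0.05))
  # positions strictly increasing within scaffold
  for (sc in unique(panel$loci$scaffold)) {
    pos <- panel$loci$pos[panel$loci$scaffold == sc]
    expect_true(all(diff(pos) > 0))
  }
  # duplicated-position invariant enforced by the container
  expect_error(geno_matrix(matrix(0, 2, 2),
                           data.frame(scaffold = "a", pos = c(5, 5))),
               "identical")
  # mean r2 at distances beyond 5x the decay scale is negligible
  r2_far <- numeric(0)
  for (s in 1:20) {
    cfg <- tiny_config(seed = 100 + s, n_scaffolds = 6,
                       snps_per_scaffold = 10, scaffold_length_bp = 30000,
                       ld_decay_bp = 1500)
    p <- simulate_founder_haplotypes(cfg)
    for (sc in unique(p$loci$scaffold)) {
      idx <- which(p$loci$scaffold == sc)
      A <- p$alleles[, idx]
      poly <- apply(A, 2, sd) > 0
      C <- suppressWarnings(cor(A[, poly]))^2
      D <- abs(outer(p$loci$pos[idx][poly], p$loci$pos[idx][poly], "-"))
      far <- upper.tri(C) & D >= 5 * 1500
      r2_far <- c(r2_far, C[far])
    }
  }
  expect_gt(length(r2_far), 100)
  expect_lt(mean(r2_far), 0.05)
})

test_that("progeny respect Mendelian transmission and the RCBD design", {
  cfg <- tiny_config(seed = 11, phenotype_missing_rate = 0)
  panel <- simulate_founder_haplotypes(cfg)
  prog <- simulate_progeny(panel, cfg)
  expect_equal(nrow(prog$genotypes$codes), cfg$n_trees)
  # maternal gamete allele always present in the mother's genotype
  mh <- prog$mother_haplotypes
  mat_layer <- prog$genotypes$phase[, , 1]
  for (t in sample(nrow(mat_layer), 20)) {
    mom <- prog$mother_of[t]
    mom_geno <- panel$alleles[mh[mom, 1], ] + panel$alleles[mh[mom, 2], ]
    # allele 1 requires mother to carry >=1 copy; allele 0 requires <=1
    expect_true(all(mat_layer[t, mom_geno == 2] == 1))
    expect_true(all(mat_layer[t, mom_geno == 0] == 0))
  }
  # phase consistency: layers sum to code + 1
  expect_equal(prog$genotypes$phase[, , 1] + prog$genotypes$phase[, , 2] - 1L,
               unname(prog$genotypes$codes), ignore_attr = TRUE)
  # too many mothers for the founder pool
  cfg_bad <- tiny_config(n_mothers = 60, n_founder_haplotypes = 80)
  expect_error(simulate_progeny(simulate_founder_haplotypes(cfg_bad), cfg_bad),
               "founder")
})

test_that("half-sib families show ~0.25 mean genomic relationship", {
  vals <- sapply(1:5, function(s) {
    cfg <- tiny_config(seed = 200 + s, n_mothers = 15,
                       progeny_per_family_per_block = 4, n_blocks = 2,
                       n_scaffolds = 25, snps_per_scaffold = 12)
    prog <- simulate_progeny(simulate_founder_haplotypes(cfg), cfg)
    A <- suppressWarnings(vanraden_a_matrix(prog$genotypes$codes))$matrix
    ped <- prog$pedigree
    same <- outer(ped$mother_id, ped$mother_id, "==")
    ut <- upper.tri(A)
    c(sib = mean(A[same & ut]), unrel = mean(A[!same & ut]))
  })
  expect_true(abs(mean(vals["sib", ]) - 0.25) < 0.05)
  expect_lt(abs(mean(vals["unrel", ])), 0.05)
})

test_that("trait architectures realize the configured variance fractions", {
  cfg <- tiny_config(seed = 5, n_mothers = 50, n_founder_haplotypes = 150,
                     progeny_per_family_per_block = 5, n_blocks = 8,
                     n_qtl_additive = 40, n_qtl_epistatic_pairs = 20,
                     h2_additive = 0.35, h2_epistatic = 0.2,
                     spatial_variance_fraction = 0)
  prog <- simulate_progeny(simulate_founder_haplotypes(cfg), cfg)
  tr <- simulate_trait(prog$genotypes, cfg)
  X <- prog$genotypes$codes
  g_add <- drop(X[, tr$architecture$additive_qtl$locus] %*%
                  tr$architecture$additive_qtl$effect)
  expect_equal(var(g_add), 0.35, tolerance = 1e-6)
  # zero heritability collapses to the intercept
  cfg0 <- tiny_config(seed = 5, h2_additive = 0, h2_epistatic = 0)
  tr0 <- simulate_trait(prog$genotypes, cfg0)
  expect_true(all(tr0$values == tr0$architecture$intercept))
  # more QTL than loci
  cfg_bad <- tiny_config(n_qtl_additive = 10000)
  expect_error(simulate_trait(prog$genotypes, cfg_bad), "exceeds")
})

test_that("phenotype regresses on true genetic value with slope ~1 and h2 in band", {
  cfg <- tiny_config(seed = 21, n_mothers = 50, n_founder_haplotypes = 150,
                     progeny_per_family_per_block = 5, n_blocks = 8,
                     n_scaffolds = 30, snps_per_scaffold = 10,
                     h2_additive = 0.35, h2_epistatic = 0,
                     spatial_variance_fraction = 0,
                     phenotype_missing_rate = 0)
  prog <- simulate_progeny(simulate_founder_haplotypes(cfg), cfg)
  tr <- simulate_trait(prog$genotypes, cfg)
  ph <- simulate_field(list(T1 = tr), prog$pedigree, cfg)
  slope <- coef(lm(ph$T1 ~ tr$values))[2]
  expect_equal(unname(slope), 1, tolerance = 0.15)
  h2_real <- var(tr$values) / var(ph$T1)
  expect_gt(h2_real, 0.30)
  expect_lt(h2_real, 0.40)
})

test_that("a major dominant QTL produces a detectably bimodal phenotype", {
  cfg <- tiny_config(seed = 8, n_mothers = 40,
                     progeny_per_family_per_block = 4, n_blocks = 4,
                     h2_additive = 0.3, bimodal_major_qtl = TRUE,
                     spatial_variance_fraction = 0, phenotype_missing_rate = 0)
  prog <- simulate_progeny(simulate_founder_haplotypes(cfg), cfg)
  tr <- simulate_trait(prog$genotypes, cfg)
  ph <- simulate_field(list(T1 = tr), prog$pedigree, cfg)
  # two-component separation: k-means split distance vs within-cluster spread
  km <- kmeans(ph$T1, centers = range(ph$T1), iter.max = 50)
  sep <- abs(diff(km$centers)) /
    max(tapply(ph$T1, km$cluster, sd))
  expect_gt(sep, 2)
  # without the flag the same statistic stays low
  cfg0 <- tiny_config(seed = 8, h2_additive = 0.3, bimodal_major_qtl = FALSE,
                      n_mothers = 40, progeny_per_family_per_block = 4,
                      n_blocks = 4, spatial_variance_fraction = 0,
                      phenotype_missing_rate = 0)
  tr0 <- simulate_trait(prog$genotypes, cfg0)
  ph0 <- simulate_field(list(T1 = tr0), prog$pedigree, cfg0)
  km0 <- kmeans(ph0$T1, centers = range(ph0$T1), iter.max = 50)
  sep0 <- abs(diff(km0$centers)) / max(tapply(ph0$T1, km0$cluster, sd))
  expect_lt(sep0, sep)
})

test_that("field layout is RCBD with the expected missingness", {
  cfg <- tiny_config(seed = 13, phenotype_missing_rate = 0.23)
  trial <- simulate_trial(cfg, trait_specs = list(
    T1 = list(h2_additive = 0.3, h2_epistatic = 0,
              bimodal_major_qtl = FALSE)))
  ph <- trial$phenotypes
  # every family appears exactly progeny_per_family_per_block times per block
  tab <- table(ph$block, ph$mother_id)
  expect_true(all(tab == cfg$progeny_per_family_per_block))
  # no two trees share a position
  expect_false(anyDuplicated(ph[, c("row", "col")]) > 0)
  # missing rate close to binomial expectation
  expect_equal(mean(is.na(ph$T1)), 0.23,
               tolerance = 3 * sqrt(0.23 * 0.77 / nrow(ph)))
  # spatial_variance_fraction = 0 means phenotype = genetic + iid noise:
  # the fitted surface explains (almost) nothing
  cfg0 <- tiny_config(seed = 14, spatial_variance_fraction = 0,
                      phenotype_missing_rate = 0, n_mothers = 30,
                      progeny_per_family_per_block = 4, n_blocks = 4)
  t0 <- simulate_trial(cfg0, trait_specs = list(
    T1 = list(h2_additive = 0.3, h2_epistatic = 0,
              bimodal_major_qtl = FALSE)))
  mod <- fit_spatial_spline(t0$phenotypes, "T1", knots = c(8, 8))
  expect_lt(var(mod$surface) / var(t0$phenotypes$T1), 0.05)
})

test_that("fixtures round-trip losslessly and deterministically", {
  cfg <- tiny_config(seed = 17)
  trial <- simulate_trial(cfg, n_genotyped = 60)
  d1 <- withr::local_tempdir()
  files <- write_fixture(trial$genotypes, trial$phenotypes, d1, config = cfg)
  g2 <- suppressMessages(read_vcf(files["vcf"]))
  expect_equal(unname(g2$codes), unname(trial$genotypes$codes))
  expect_false(is.null(g2$phase))
  # phased heterozygotes preserved with orientation
  expect_equal(unname(g2$phase), unname(trial$genotypes$phase))
  # byte-identical re-simulation from the manifest seed
  man <- jsonlite::read_json(files["manifest"])
  cfg2 <- do.call(sim_config, man$config[names(formals(sim_config))])
  trial2 <- simulate_trial(cfg2, n_genotyped = 60)
  d2 <- withr::local_tempdir()
  write_fixture(trial2$genotypes, trial2$phenotypes, d2, config = cfg2)
  expect_identical(readLines(file.path(d1, "genotypes.vcf")),
                   readLines(file.path(d2, "genotypes.vcf")))
  # id mismatch rejected
  bad <- trial$phenotypes[trial$phenotypes$tree_id !=
                            rownames(trial$genotypes$codes)[1], ]
  expect_error(write_fixture(trial$genotypes, bad, tempfile()), "id mismatch")
})
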