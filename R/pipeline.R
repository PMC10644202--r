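#' Default configuration for the end-to-end pipeline
#'
#' Stage blocks mirror the analysis order: simulate, qc, adjust,
#' heritability, gwas, benchmark. The defaults describe a desk-scale demo
#' trial (a few hundred trees, a few hundred SNPs) so the whole pipeline
#' runs in minutes on one CPU; every threshold of the full-scale analysis is
#' exposed here.
#'
#' @param seed master seed; each stage derives a named sub-stream.
#' @param simulate,qc,adjust,heritability,gwas,benchmark named lists
#'   overriding individual defaults of each stage block.
#' @return validated `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, simulate = list(), qc = list(),
                            adjust = list(), heritability = list(),
                            gwas = list(), benchmark = list()) {
  defaults <- list(
    seed = seed,
    simulate = list(n_mothers = 40, progeny_per_family_per_block = 2,
                    n_blocks = 4, n_founder_haplotypes = 120,
                    n_scaffolds = 40, snps_per_scaffold = 15,
                    scaffold_length_bp = 40000, ld_decay_bp = 2300,
                    maf_min = 0.05, n_qtl_additive = 60,
                    n_qtl_epistatic_pairs = 30,
                    spatial_variance_fraction = 0.10,
                    phenotype_missing_rate = 0.15, n_genotyped = 240),
    qc = list(max_missing = 0.95, maf_min = 0.05, hwe_p_min = 0.001,
              max_sample_missing = 0.65, thin_bp = 1000,
              impute_method = "mean"),
    adjust = list(knots = c(8, 8), grubbs_alpha = 0.05),
    heritability = list(n_chains = 3, n_iter = 2000, burn_in = 500,
                        thin = 5),
    gwas = list(n_pcs = 4),
    benchmark = list(methods = c("gblup", "brr", "rkhs", "rf"),
                     n_splits = 2, n_model_replicates = 2,
                     subset_sizes = c("48", "all"), ml_budget = 2,
                     bayes_n_iter = 1500, bayes_burn_in = 500))
  cfg <- defaults
  user <- list(simulate = simulate, qc = qc, adjust = adjust,
               heritability = heritability, gwas = gwas,
               benchmark = benchmark)
  for (block in names(user)) {
    unknown <- setdiff(names(user[[block]]), names(defaults[[block]]))
    if (length(unknown))
      stop(sprintf("unknown key(s) in '%s' block: %s", block,
                   paste(unknown, collapse = ", ")))
    cfg[[block]] <- modifyList(cfg[[block]], user[[block]])
  }
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  q <- cfg$qc
  if (q$maf_min <= 0 || q$maf_min > 0.5)
    stop("config validation: qc$maf_min must be in (0, 0.5]")
  if (q$max_missing < 0 || q$max_missing > 1)
    stop("config validation: qc$max_missing must be in [0, 1]")
  if (q$hwe_p_min < 0 || q$hwe_p_min > 1)
    stop("config validation: qc$hwe_p_min must be in [0, 1]")
  if (cfg$adjust$grubbs_alpha <= 0 || cfg$adjust$grubbs_alpha >= 1)
    stop("config validation: adjust$grubbs_alpha must be in (0, 1)")
  if (cfg$heritability$n_chains < 1)
    stop("config validation: heritability$n_chains must be >= 1")
  # simulate block is validated by sim_config() at run time
  invisible(cfg)
}

write_provenance <- function(dir, stage, seed, inputs, outputs) {
  md5_by_name <- function(files) {
    h <- tools::md5sum(files)
    as.list(setNames(unname(h), basename(files)))
  }
  prov <- list(stage = stage, seed = seed,
               package = "progenyGS",
               version = as.character(utils::packageVersion("progenyGS")),
               inputs = md5_by_name(inputs),
               outputs = md5_by_name(outputs))
  path <- file.path(dir, paste0(stage, ".provenance.json"))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' Run the full simulate -> qc -> adjust -> heritability -> gwas -> benchmark
#' pipeline
#'
#' Each stage writes plain-text outputs plus a provenance record (stage
#' seed, package version, input/output checksums). No timestamps are
#' recorded, so rerunning with an identical configuration reproduces the
#' artifact directory bit-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return invisible list with the main in-memory results per stage.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- simulate ---------------------------------------------------------
  sim_dir <- file.path(out_dir, "sim")
  sim <- run_stage("simulate", {
    sc <- config$simulate
    cfg <- sim_config(
      n_mothers = sc$n_mothers,
      progeny_per_family_per_block = sc$progeny_per_family_per_block,
      n_blocks = sc$n_blocks, n_founder_haplotypes = sc$n_founder_haplotypes,
      n_scaffolds = sc$n_scaffolds, snps_per_scaffold = sc$snps_per_scaffold,
      scaffold_length_bp = sc$scaffold_length_bp,
      ld_decay_bp = sc$ld_decay_bp, maf_min = sc$maf_min,
      n_qtl_additive = sc$n_qtl_additive,
      n_qtl_epistatic_pairs = sc$n_qtl_epistatic_pairs,
      spatial_variance_fraction = sc$spatial_variance_fraction,
      phenotype_missing_rate = sc$phenotype_missing_rate,
      seed = substream_seed(config$seed, "simulate"))
    trial <- simulate_trial(cfg, n_genotyped = sc$n_genotyped)
    files <- write_fixture(trial$genotypes, trial$phenotypes, sim_dir,
                           config = cfg)
    write_provenance(sim_dir, "simulate", cfg$seed, character(0), files)
    trial
  })

  # --- qc ---------------------------------------------------------------
  qc_dir <- file.path(out_dir, "qc")
  dir.create(qc_dir, showWarnings = FALSE)
  qc <- run_stage("qc", {
    q <- config$qc
    vcf_in <- file.path(sim_dir, "genotypes.vcf")
    g <- read_vcf(vcf_in)
    g <- filter_samples(g, q$max_sample_missing)
    g <- filter_sites(g, q$max_missing, q$maf_min, q$hwe_p_min)
    g <- remove_solitary_snps(g)
    g <- impute_missing(g, q$impute_method)
    vcf_out <- file.path(qc_dir, "filtered.vcf")
    write_geno_vcf(g, vcf_out)
    g_thin <- thin_by_distance(g, q$thin_bp)
    pca <- genotype_pca(g_thin, n_pcs = 10)
    pca_tsv <- file.path(qc_dir, "pca.tsv")
    write.table(data.frame(sample = rownames(pca$coordinates),
                           pca$coordinates, check.names = FALSE),
                pca_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    set.seed(substream_seed(config$seed, "qc_ld"))
    ld <- pairwise_ld(g_thin, max_pairs_per_scaffold = 500)
    ld_tsv <- file.path(qc_dir, "ld.tsv")
    write.table(ld, ld_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    decay <- tryCatch(ld_decay(ld), error = function(e) NULL)
    summ <- list(n_samples = nrow(g$codes), n_loci = ncol(g$codes),
                 n_thinned = ncol(g_thin$codes),
                 pc1_pct = pca$var_explained_pct[1],
                 pc2_pct = pca$var_explained_pct[2],
                 ld_decay_bp = if (!is.null(decay)) decay$decay_bp else NA)
    jsonlite::write_json(summ, file.path(qc_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_provenance(qc_dir, "qc", substream_seed(config$seed, "qc_ld"),
                     vcf_in, c(vcf_out, pca_tsv, ld_tsv))
    list(genotypes = g, thinned = g_thin, pca = pca, ld = ld,
         decay = decay)
  })

  # --- adjust -----------------------------------------------------------
  adj_dir <- file.path(out_dir, "adjust")
  dir.create(adj_dir, showWarnings = FALSE)
  traits <- setdiff(names(sim$architectures), character(0))
  adjusted <- run_stage("adjust", {
    pheno_path <- file.path(sim_dir, "phenotypes.tsv")
    pheno <- read.table(pheno_path, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    for (tn in traits) {
      model <- fit_spatial_spline(pheno, tn, knots = config$adjust$knots)
      pheno <- adjust_phenotypes(pheno, model)
      obs <- which(!is.na(pheno[[tn]]))
      gr <- grubbs_filter(setNames(pheno[[tn]][obs], obs),
                          alpha = config$adjust$grubbs_alpha)
      if (length(gr$removed))
        pheno[[tn]][as.integer(gr$removed)] <- NA
    }
    out_tsv <- file.path(adj_dir, "adjusted_phenotypes.tsv")
    write.table(pheno, out_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(adj_dir, "adjust", config$seed, pheno_path, out_tsv)
    pheno
  })

  # --- heritability -----------------------------------------------------
  her_dir <- file.path(out_dir, "heritability")
  dir.create(her_dir, showWarnings = FALSE)
  heritability <- run_stage("heritability", {
    h <- config$heritability
    g <- qc$genotypes
    idx <- match(rownames(g$codes), adjusted$tree_id)
    res <- lapply(traits, function(tn) {
      spec <- bayes_spec("BRR", n_iter = h$n_iter, burn_in = h$burn_in,
                         thin = h$thin,
                         seed = substream_seed(config$seed, "h2", match(tn, traits)))
      est <- genomic_heritability(adjusted[[tn]][idx], g$codes,
                                  spec, n_chains = h$n_chains)
      list(trait = tn, h2 = est$h2, per_chain = unname(est$per_chain),
           n = est$n)
    })
    names(res) <- traits
    out_json <- file.path(her_dir, "heritability.json")
    jsonlite::write_json(res, out_json, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    write_provenance(her_dir, "heritability", config$seed, character(0),
                     out_json)
    res
  })

  # --- gwas (all individuals) ------------------------------------------
  gwas_dir <- file.path(out_dir, "gwas")
  dir.create(gwas_dir, showWarnings = FALSE)
  gwas <- run_stage("gwas", {
    g <- qc$genotypes
    idx <- match(rownames(g$codes), adjusted$tree_id)
    res <- list()
    for (tn in traits) {
      y <- adjusted[[tn]][idx]
      keep <- which(!is.na(y))
      gk <- subset_geno(g, samples = keep)
      kin <- suppressWarnings(vanraden_a_matrix(gk$codes))
      scan <- mixed_scan(y[keep], gk, kin, n_pcs = config$gwas$n_pcs)
      out_tsv <- file.path(gwas_dir, paste0("gwas_", tn, ".tsv"))
      write.table(as.data.frame(scan), out_tsv, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      res[[tn]] <- scan
    }
    write_provenance(gwas_dir, "gwas", config$seed, character(0),
                     file.path(gwas_dir, paste0("gwas_", traits, ".tsv")))
    res
  })

  # --- benchmark --------------------------------------------------------
  bm_dir <- file.path(out_dir, "benchmark")
  dir.create(bm_dir, showWarnings = FALSE)
  benchmark <- run_stage("benchmark", {
    b <- config$benchmark
    g <- qc$genotypes
    # drop traits that lost too many samples to run 3:1 splits
    plan <- cv_plan(n_samples = nrow(g$codes), traits = traits,
                    methods = b$methods, n_splits = b$n_splits,
                    n_model_replicates = b$n_model_replicates,
                    subset_sizes = b$subset_sizes,
                    master_seed = substream_seed(config$seed, "benchmark"),
                    ml_budget = b$ml_budget,
                    bayes_mcmc = list(n_iter = b$bayes_n_iter,
                                      burn_in = b$bayes_burn_in, thin = 5))
    bm <- run_benchmark(list(genotypes = g, phenotypes = adjusted), plan)
    res_tsv <- file.path(bm_dir, "benchmark_long.tsv")
    med_tsv <- file.path(bm_dir, "benchmark_medians.tsv")
    write.table(bm$results, res_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(bm$medians, med_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_provenance(bm_dir, "benchmark", plan$master_seed, character(0),
                     c(res_tsv, med_tsv))
    bm
  })

  invisible(list(sim = sim, qc = qc, adjusted = adjusted,
                 heritability = heritability, gwas = gwas,
                 benchmark = benchmark, out_dir = out_dir))
}
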