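#' Configuration for the half-sib progeny-trial simulator
#'
#' Defaults describe the trial design the package emulates: 94 open-pollinated
#' mother trees, 5 progeny per family per block in 8 randomized complete
#' blocks (3760 trees), ~18,000 biallelic SNPs spread over many short
#' scaffolds with linkage disequilibrium decaying to r2 = 0.1 around 2.3 kb,
#' narrow-sense heritabilities around 0.35, a smooth spatial micro-environment
#' surface, 6 x 3 m planting spacing, and phenotype missingness from thinning
#' and mortality.
#'
#' Traits are simulated on a unit-variance scale: `h2_additive`,
#' `h2_epistatic` and `spatial_variance_fraction` are fractions of the
#' phenotypic variance, and the residual standard deviation is derived as
#' `sqrt(1 - h2_additive - h2_epistatic - spatial_variance_fraction)`.
#'
#' @param n_mothers number of open-pollinated mother trees (families).
#' @param progeny_per_family_per_block trees per family within each block.
#' @param n_blocks number of RCBD blocks.
#' @param n_founder_haplotypes size of the founder haplotype pool the mothers
#'   and unrecorded fathers are drawn from.
#' @param n_scaffolds,snps_per_scaffold,scaffold_length_bp genome layout.
#' @param ld_decay_bp distance at which pairwise r2 decays to 0.1.
#' @param maf_min founder minor-allele-frequency floor.
#' @param n_qtl_additive,n_qtl_epistatic_pairs trait architecture sizes.
#' @param h2_additive,h2_epistatic target variance fractions.
#' @param spatial_variance_fraction variance fraction of the smooth field
#'   surface.
#' @param bimodal_major_qtl add one large, dominant-acting QTL producing a
#'   bimodal phenotype distribution.
#' @param row_spacing_m,col_spacing_m planting spacing in metres.
#' @param phenotype_missing_rate fraction of trees with missing phenotypes.
#' @param seed master seed; every stage derives a named sub-stream from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_mothers = 94, progeny_per_family_per_block = 5,
                       n_blocks = 8, n_founder_haplotypes = 200,
                       n_scaffolds = 600, snps_per_scaffold = 30,
                       scaffold_length_bp = 40000, ld_decay_bp = 2300,
                       maf_min = 0.05, n_qtl_additive = 100,
                       n_qtl_epistatic_pairs = 50, h2_additive = 0.35,
                       h2_epistatic = 0, spatial_variance_fraction = 0.10,
                       bimodal_major_qtl = FALSE, row_spacing_m = 3,
                       col_spacing_m = 6, phenotype_missing_rate = 0.23,
                       seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_mothers, progeny_per_family_per_block, n_blocks,
              n_founder_haplotypes, n_scaffolds, snps_per_scaffold,
              scaffold_length_bp, ld_decay_bp)
  if (any(counts <= 0)) stop("invalid config: all counts must be positive")
  if (snps_per_scaffold < 2)
    stop("invalid config: snps_per_scaffold must be at least 2")
  if (maf_min <= 0 || maf_min > 0.5)
    stop("invalid config: maf_min must be in (0, 0.5]")
  if (h2_additive < 0 || h2_epistatic < 0 || spatial_variance_fraction < 0 ||
      h2_additive + h2_epistatic + spatial_variance_fraction >= 1)
    stop("invalid config: variance fractions must be non-negative and sum below 1")
  if (phenotype_missing_rate < 0 || phenotype_missing_rate >= 1)
    stop("invalid config: phenotype_missing_rate must be in [0, 1)")
  cfg$n_trees <- n_mothers * progeny_per_family_per_block * n_blocks
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate founder haplotypes with distance-dependent linkage disequilibrium
#'
#' Haplotypes are generated per scaffold by a first-order Markov copying
#' chain: the allele at each locus is copied from the previous locus with
#' probability `exp(-d * log(10) / (2 * ld_decay_bp))` (`d` = inter-locus
#' distance in bp) and redrawn from the scaffold allele frequency otherwise,
#' so that pairwise haplotype r2 decays as `exp(-2d/s)` and crosses 0.1 at
#' `ld_decay_bp`. Realized minor allele frequencies below `maf_min` are
#' repaired by flipping majority alleles in randomly chosen haplotypes.
#'
#' @param config a [sim_config()].
#' @return a `haplotype_panel`: binary founder-haplotype x locus matrix plus
#'   locus metadata (scaffold, position, founder allele frequency).
#' @export
simulate_founder_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$snps_per_scaffold < 2)
    stop("invalid config: snps_per_scaffold must be at least 2")
  set.seed(substream_seed(config$seed, "founders"))
  H <- config$n_founder_haplotypes
  Ls <- config$snps_per_scaffold
  rho_scale <- 2 * config$ld_decay_bp / log(10)

  alleles <- matrix(0L, H, config$n_scaffolds * Ls)
  scaffold <- character(config$n_scaffolds * Ls)
  pos <- integer(config$n_scaffolds * Ls)
  freq <- numeric(config$n_scaffolds * Ls)
  floor_count <- max(1L, ceiling(config$maf_min * H))

  for (s in seq_len(config$n_scaffolds)) {
    idx <- (s - 1L) * Ls + seq_len(Ls)
    p <- runif(1, max(config$maf_min, 0.1), 0.5)
    ppos <- sort(sample.int(config$scaffold_length_bp, Ls))
    hap <- matrix(0L, H, Ls)
    hap[, 1] <- rbinom(H, 1, p)
    if (Ls > 1) {
      rho <- exp(-diff(ppos) / rho_scale)
      for (l in 2:Ls) {
        copy <- runif(H) < rho[l - 1]
        hap[, l] <- ifelse(copy, hap[, l - 1], rbinom(H, 1, p))
      }
    }
    # minor-allele floor repair
    for (l in seq_len(Ls)) {
      repeat {
        n1 <- sum(hap[, l])
        minor_is_alt <- n1 <= H - n1
        n_minor <- min(n1, H - n1)
        if (n_minor >= floor_count) break
        major <- which(hap[, l] == as.integer(!minor_is_alt))
        hap[sample(major, 1), l] <- as.integer(minor_is_alt)
      }
    }
    alleles[, idx] <- hap
    scaffold[idx] <- sprintf("scaffold_%04d", s)
    pos[idx] <- ppos
    freq[idx] <- colMeans(hap)
  }
  loci <- data.frame(id = paste0(scaffold, "_", pos), scaffold = scaffold,
                     pos = pos, ref = "A", alt = "G", freq = freq,
                     stringsAsFactors = FALSE)
  if (anyDuplicated(loci[, c("scaffold", "pos")]))
    stop("two loci at identical position generated; increase scaffold_length_bp")
  structure(list(alleles = alleles, loci = loci), class = "haplotype_panel")
}

# vectorized recombinant gametes: Haldane map from a Poisson crossover
# process with expectation 1 crossover per scaffold.
# parent_a/parent_b: n_gametes x L allele matrices (the two parental strands)
recombinant_gametes <- function(parent_a, parent_b, loci, scaffold_length_bp) {
  n <- nrow(parent_a)
  L <- ncol(parent_a)
  gam <- matrix(0L, n, L)
  rate <- 1 / scaffold_length_bp # crossovers per bp
  for (sc in unique(loci$scaffold)) {
    idx <- which(loci$scaffold == sc)
    d <- diff(loci$pos[idx])
    q <- (1 - exp(-2 * rate * d)) / 2 # Haldane recombination fraction
    strand <- matrix(0L, n, length(idx))
    strand[, 1] <- rbinom(n, 1, 0.5)
    if (length(idx) > 1) {
      for (l in 2:length(idx)) {
        sw <- rbinom(n, 1, q[l - 1])
        strand[, l] <- (strand[, l - 1] + sw) %% 2L
      }
    }
    gam[, idx] <- ifelse(strand == 0L, parent_a[, idx, drop = FALSE],
                         parent_b[, idx, drop = FALSE])
  }
  gam
}

#' Simulate open-pollinated half-sib progeny
#'
#' Each mother is a random pair of founder haplotypes. Every offspring
#' receives one recombinant maternal gamete and one recombinant gamete from a
#' random, unrecorded founder father (open pollination). Phase of the two
#' gametes is retained (layer 1 = maternal, layer 2 = paternal); the pedigree
#' records the mother only.
#'
#' @param panel a `haplotype_panel` from [simulate_founder_haplotypes()].
#' @param config a [sim_config()].
#' @return list with `genotypes` (a phased [geno_matrix()]) and `pedigree`
#'   (data.frame `tree_id`, `mother_id`, `block`).
#' @export
simulate_progeny <- function(panel, config) {
  stopifnot(inherits(panel, "haplotype_panel"), inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "progeny"))
  H <- nrow(panel$alleles)
  if (config$n_mothers > floor(H / 2))
    stop("n_mothers exceeds available founder haplotype pairs")
  L <- nrow(panel$loci)
  n <- config$n_trees

  mother_haps <- matrix(sample.int(H, 2 * config$n_mothers), ncol = 2)
  mother_of <- rep(rep(seq_len(config$n_mothers),
                       each = config$progeny_per_family_per_block),
                   times = config$n_blocks)
  block_of <- rep(seq_len(config$n_blocks),
                  each = config$n_mothers * config$progeny_per_family_per_block)

  mat <- recombinant_gametes(panel$alleles[mother_haps[mother_of, 1], , drop = FALSE],
                             panel$alleles[mother_haps[mother_of, 2], , drop = FALSE],
                             panel$loci, config$scaffold_length_bp)
  father_a <- sample.int(H, n, replace = TRUE)
  father_b <- sample.int(H, n, replace = TRUE)
  pat <- recombinant_gametes(panel$alleles[father_a, , drop = FALSE],
                             panel$alleles[father_b, , drop = FALSE],
                             panel$loci, config$scaffold_length_bp)

  codes <- mat + pat - 1L
  rownames(codes) <- sprintf("t%05d", seq_len(n))
  phase <- array(0L, c(n, L, 2))
  phase[, , 1] <- mat
  phase[, , 2] <- pat
  g <- geno_matrix(codes, panel$loci[, c("id", "scaffold", "pos", "ref", "alt")],
                   phase)
  pedigree <- data.frame(tree_id = rownames(codes),
                         mother_id = sprintf("m%03d", mother_of),
                         block = block_of, stringsAsFactors = FALSE)
  list(genotypes = g, pedigree = pedigree, mother_haplotypes = mother_haps,
       mother_of = mother_of)
}

#' Simulate a trait architecture and per-tree genetic values
#'
#' Genetic value = sum of additive effects on the \{-1, 0, 1\} coding plus
#' pairwise genotype products for epistatic pairs, each component rescaled so
#' its realized variance over the simulated population equals the configured
#' fraction of the unit phenotypic variance. With `bimodal_major_qtl` a single
#' dominant-acting major QTL (carrier vs non-carrier, sd 1.2) is added on top,
#' producing a bimodal phenotype distribution.
#'
#' @param genotypes a [geno_matrix()] of the simulated trees.
#' @param config a [sim_config()].
#' @param name trait name used to derive the random sub-stream.
#' @return list with `values` (genetic value per tree) and `architecture`
#'   (QTL positions and effects, intercept, residual sd).
#' @export
simulate_trait <- function(genotypes, config, name = "trait") {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(config, "sim_config"))
  X <- genotypes$codes
  m <- ncol(X)
  if (all(apply(X, 2, var) == 0)) stop("genotypes are monomorphic")
  if (config$n_qtl_additive > m)
    stop("n_qtl_additive exceeds the number of loci")
  set.seed(substream_seed(config$seed, paste0("trait_", name)))

  g_add <- numeric(nrow(X))
  add_qtl <- integer(0); add_eff <- numeric(0)
  if (config$h2_additive > 0 && config$n_qtl_additive > 0) {
    add_qtl <- sort(sample.int(m, config$n_qtl_additive))
    add_eff <- rnorm(length(add_qtl))
    g_add <- drop(X[, add_qtl, drop = FALSE] %*% add_eff)
    sc <- sqrt(config$h2_additive / var(g_add))
    add_eff <- add_eff * sc
    g_add <- g_add * sc
  }

  g_epi <- numeric(nrow(X))
  epi_pairs <- matrix(integer(0), 0, 2); epi_eff <- numeric(0)
  if (config$h2_epistatic > 0 && config$n_qtl_epistatic_pairs > 0) {
    if (2 * config$n_qtl_epistatic_pairs > m)
      stop("n_qtl_epistatic_pairs exceeds the number of loci")
    picks <- sample.int(m, 2 * config$n_qtl_epistatic_pairs)
    epi_pairs <- matrix(picks, ncol = 2)
    W <- X[, epi_pairs[, 1], drop = FALSE] * X[, epi_pairs[, 2], drop = FALSE]
    epi_eff <- rnorm(nrow(epi_pairs))
    g_epi <- drop(W %*% epi_eff)
    v <- var(g_epi)
    if (v > 0) {
      sc <- sqrt(config$h2_epistatic / v)
      epi_eff <- epi_eff * sc
      g_epi <- g_epi * sc
    }
  }

  g_major <- numeric(nrow(X))
  major <- NULL
  if (isTRUE(config$bimodal_major_qtl)) {
    p_alt <- colMeans(X + 1) / 2
    maf <- pmin(p_alt, 1 - p_alt)
    major <- which.min(abs(maf - 0.35))
    carrier <- as.numeric(X[, major] > -0.5) # dominant action
    if (var(carrier) > 0)
      g_major <- 1.2 * (carrier - mean(carrier)) / sd(carrier)
  }

  residual_sd <- sqrt(max(1 - config$h2_additive - config$h2_epistatic -
                            config$spatial_variance_fraction, 0.02))
  list(values = g_add + g_epi + g_major,
       architecture = list(
         additive_qtl = data.frame(locus = add_qtl, effect = add_eff),
         epistatic_pairs = if (nrow(epi_pairs))
           data.frame(locus1 = epi_pairs[, 1], locus2 = epi_pairs[, 2],
                      effect = epi_eff)
         else data.frame(locus1 = integer(0), locus2 = integer(0),
                         effect = numeric(0)),
         major_qtl = major, intercept = 0, residual_sd = residual_sd))
}

#' Place trees on an RCBD field grid and add spatial and residual noise
#'
#' Families are randomized within each block; blocks are tiled along the row
#' axis. A smooth low-frequency surface (a sum of six random two-dimensional
#' cosine components, rescaled so its variance equals
#' `spatial_variance_fraction`) is shared by all traits, and independent
#' Gaussian residuals with the architecture's residual sd are added per
#' trait. A fraction `phenotype_missing_rate` of trees is set missing for all
#' traits, emulating thinning and mortality.
#'
#' @param traits named list of [simulate_trait()] results (one per trait).
#' @param pedigree pedigree data.frame from [simulate_progeny()].
#' @param config a [sim_config()].
#' @return a phenotype table: `tree_id`, `mother_id`, `block`, `row`, `col`,
#'   metre coordinates `x_m`, `y_m`, one column per trait, and the latent
#'   `spatial` effect (kept for diagnostics).
#' @export
simulate_field <- function(traits, pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(traits$values)) traits <- list(trait = traits)
  n <- nrow(pedigree)
  if (any(vapply(traits, function(t) length(t$values), 1L) != n))
    stop("genetic value length does not equal the number of trees")
  set.seed(substream_seed(config$seed, "field"))

  per_block <- config$n_mothers * config$progeny_per_family_per_block
  ncol_b <- ceiling(sqrt(per_block))
  nrow_b <- ceiling(per_block / ncol_b)
  if (nrow_b * ncol_b < per_block) stop("field grid too small for all trees")

  row <- integer(n); col <- integer(n)
  for (b in seq_len(config$n_blocks)) {
    in_b <- which(pedigree$block == b)
    slots <- sample.int(nrow_b * ncol_b, length(in_b))
    row[in_b] <- (b - 1L) * nrow_b + ((slots - 1L) %/% ncol_b) + 1L
    col[in_b] <- ((slots - 1L) %% ncol_b) + 1L
  }
  x <- (col - 1) * config$col_spacing_m
  y <- (row - 1) * config$row_spacing_m

  spatial <- numeric(n)
  if (config$spatial_variance_fraction > 0) {
    ext_x <- max(max(x), 1); ext_y <- max(max(y), 1)
    s <- numeric(n)
    for (k in 1:6) {
      fx <- runif(1, 0.5 / ext_x, 3 / ext_x)
      fy <- runif(1, 0.5 / ext_y, 3 / ext_y)
      s <- s + rnorm(1) * cos(2 * pi * (fx * x + fy * y) + runif(1, 0, 2 * pi))
    }
    spatial <- (s - mean(s)) / sd(s) * sqrt(config$spatial_variance_fraction)
  }

  out <- data.frame(tree_id = pedigree$tree_id, mother_id = pedigree$mother_id,
                    block = pedigree$block, row = row, col = col,
                    x_m = x, y_m = y, stringsAsFactors = FALSE)
  for (tn in names(traits)) {
    tr <- traits[[tn]]
    out[[tn]] <- tr$architecture$intercept + tr$values + spatial +
      rnorm(n, 0, tr$architecture$residual_sd)
  }
  miss <- runif(n) < config$phenotype_missing_rate
  for (tn in names(traits)) out[[tn]][miss] <- NA_real_
  out$spatial <- spatial
  out
}

#' Simulate a complete progeny trial
#'
#' Convenience wrapper running founder panel, progeny, trait architectures and
#' field placement. Default traits mirror the two focal growth traits the
#' package benchmarks: `D7` (stem diameter-like; mostly additive, bimodal via
#' one dominant major QTL) and `H7` (height-like; epistasis-dominated,
#' near-normal).
#'
#' @param config a [sim_config()].
#' @param trait_specs named list; per trait a list overriding `h2_additive`,
#'   `h2_epistatic` and `bimodal_major_qtl` in `config`.
#' @param n_genotyped if non-NULL, subsample this many trees with observed
#'   phenotypes as the genotyped survivors (the field table keeps all trees).
#' @return list with `genotypes` (phased [geno_matrix()] of genotyped trees),
#'   `phenotypes`, `pedigree`, `architectures`, `panel`, `config`.
#' @export
simulate_trial <- function(config = sim_config(),
                           trait_specs = list(
                             D7 = list(h2_additive = 0.366, h2_epistatic = 0,
                                       bimodal_major_qtl = TRUE),
                             H7 = list(h2_additive = 0.10, h2_epistatic = 0.26,
                                       bimodal_major_qtl = FALSE)),
                           n_genotyped = NULL) {
  panel <- simulate_founder_haplotypes(config)
  prog <- simulate_progeny(panel, config)
  traits <- list()
  for (tn in names(trait_specs)) {
    cfg_t <- config
    for (f in names(trait_specs[[tn]])) cfg_t[[f]] <- trait_specs[[tn]][[f]]
    traits[[tn]] <- simulate_trait(prog$genotypes, cfg_t, name = tn)
  }
  pheno <- simulate_field(traits, prog$pedigree, config)
  geno <- prog$genotypes
  if (!is.null(n_genotyped)) {
    set.seed(substream_seed(config$seed, "genotyped"))
    observed <- which(!is.na(pheno[[names(trait_specs)[1]]]))
    if (n_genotyped > length(observed))
      stop("n_genotyped exceeds the number of phenotyped trees")
    keep <- sort(sample(observed, n_genotyped))
    geno <- subset_geno(geno, samples = keep)
  }
  list(genotypes = geno, phenotypes = pheno, pedigree = prog$pedigree,
       architectures = traits, panel = panel, config = config)
}

#' Write a simulated trial to plain-text fixture files
#'
#' Writes a VCF 4.2 file (phase bars when the genotypes carry phase), a
#' tab-separated phenotype table and a JSON manifest holding the seed and
#' configuration. No timestamps are written, so re-simulating with the
#' manifest seed reproduces the files byte-identically.
#'
#' @param genotypes a [geno_matrix()].
#' @param phenotypes phenotype table containing all genotyped `tree_id`s.
#' @param dir output directory (created if needed).
#' @param config optional [sim_config()] recorded in the manifest.
#' @return invisible named vector of file paths.
#' @export
write_fixture <- function(genotypes, phenotypes, dir, config = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"))
  if (!all(rownames(genotypes$codes) %in% phenotypes$tree_id))
    stop("id mismatch: genotyped samples missing from the phenotype table")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vcf <- file.path(dir, "genotypes.vcf")
  tsv <- file.path(dir, "phenotypes.tsv")
  man <- file.path(dir, "manifest.json")
  write_geno_vcf(genotypes, vcf)
  write.table(phenotypes, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(seed = if (!is.null(config)) config$seed else NA,
                   n_samples = nrow(genotypes$codes),
                   n_loci = ncol(genotypes$codes),
                   config = if (!is.null(config)) unclass(config) else NULL)
  jsonlite::write_json(manifest, man, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(vcf = vcf, tsv = tsv, manifest = man))
}

#' Write a genotype matrix as VCF 4.2
#'
#' @param g a [geno_matrix()]; fractional (imputed) codes are not writable.
#' @param path output file.
#' @export
write_geno_vcf <- function(g, path) {
  codes <- g$codes
  if (any(abs(codes - round(codes)) > 1e-8, na.rm = TRUE))
    stop("cannot write fractional (imputed) genotype codes to VCF")
  n <- nrow(codes); m <- ncol(codes)
  if (!is.null(g$phase)) {
    gt <- matrix(paste0(g$phase[, , 1], "|", g$phase[, , 2]), n, m)
  } else {
    gt <- matrix("", n, m)
    gt[codes == -1] <- "0/0"; gt[codes == 0] <- "0/1"; gt[codes == 1] <- "1/1"
  }
  gt[is.na(codes)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=progenyGS",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(codes)), collapse = "\t"))
  body <- paste(g$loci$scaffold, g$loci$pos, g$loci$id,
                g$loci$ref %||% "A", g$loci$alt %||% "G",
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
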