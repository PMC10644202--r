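#' Read a VCF into a coded genotype matrix
#'
#' Genotypes are coded -1 (homozygous reference), 0 (heterozygous),
#' 1 (homozygous alternative); `./.` becomes NA. Only biallelic SNPs are
#' kept; multiallelic or indel records are dropped with a reported count.
#' When every called genotype carries a phase bar the two gamete layers are
#' retained (reference allele = 0, alternative allele = 1).
#'
#' @param path VCF 4.x file with a GT field.
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  biallelic <- n_alt == 1L
  alt <- rep(NA_character_, length(ref))
  alt[biallelic] <- as.character(unlist(altl[biallelic]))
  snp <- biallelic & nchar(ref) == 1L & !is.na(alt) & nchar(alt) == 1L
  n_dropped <- sum(!snp)
  if (n_dropped > 0)
    message(sprintf("read_vcf: dropped %d non-biallelic-SNP record(s)", n_dropped))

  gt <- VariantAnnotation::geno(vcf)$GT[snp, , drop = FALSE] # loci x samples
  scaffold <- as.character(GenomicRanges::seqnames(rr))[snp]
  pos <- GenomicRanges::start(rr)[snp]

  a1 <- matrix(suppressWarnings(as.integer(substr(gt, 1, 1))),
               nrow(gt), ncol(gt))
  a2 <- matrix(suppressWarnings(as.integer(substr(gt, 3, 3))),
               nrow(gt), ncol(gt))
  multi_gt <- which(!is.na(a1) & !is.na(a2) & (a1 > 1 | a2 > 1))
  if (length(multi_gt)) stop("GT allele index above 1 in a biallelic record")
  codes <- t(a1 + a2 - 1L) # samples x loci
  rownames(codes) <- colnames(gt)

  loci <- data.frame(id = paste0(scaffold, "_", pos), scaffold = scaffold,
                     pos = pos, ref = ref[snp], alt = alt[snp],
                     stringsAsFactors = FALSE)

  phase <- NULL
  called <- !is.na(codes)
  if (length(gt) && all(grepl("|", t(gt)[called], fixed = TRUE))) {
    p1 <- t(a1); p2 <- t(a2)
    phase <- array(NA_integer_, c(nrow(codes), ncol(codes), 2))
    phase[, , 1] <- p1
    phase[, , 2] <- p2
  }
  geno_matrix(codes, loci, phase)
}

#' Exact Hardy-Weinberg test by full enumeration
#'
#' Two-sided exact test: the p-value is the total probability, under the
#' conditional distribution of the heterozygote count given the allele
#' counts, of all genotype configurations no more probable than the observed
#' one.
#'
#' @param n_aa,n_ab,n_bb genotype counts (homozygous ref, het, homozygous alt).
#' @return exact p-value.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n == 0 || n_a == 0 || n_b == 0) return(1)
  hets <- seq(n_ab %% 2, min(n_a, n_b), by = 2)
  logp <- lgamma(n + 1) - lgamma((n_a - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_b - hets) / 2 + 1) + hets * log(2) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  p_all <- exp(logp - max(logp))
  p_all <- p_all / sum(p_all)
  p_obs <- p_all[hets == n_ab]
  sum(p_all[p_all <= p_obs + 1e-12])
}

locus_counts <- function(codes) {
  if (any(abs(codes - round(codes)) > 1e-8, na.rm = TRUE))
    stop("genotype counts require unimputed integer codes")
  list(aa = colSums(codes == -1, na.rm = TRUE),
       ab = colSums(codes == 0, na.rm = TRUE),
       bb = colSums(codes == 1, na.rm = TRUE))
}

#' Filter loci on call rate, minor allele frequency and Hardy-Weinberg
#'
#' `max_missing` follows VCFtools `--max-missing` semantics: it is the
#' required proportion of called genotypes (0.95 keeps loci with at least 95%
#' of samples called). Depth-based criteria are not applicable to coded
#' genotypes and are not implemented.
#'
#' @param g a [geno_matrix()].
#' @param max_missing required non-missing proportion per locus.
#' @param maf_min minimum minor allele frequency (over called genotypes).
#' @param hwe_p_min minimum exact Hardy-Weinberg p-value.
#' @return filtered [geno_matrix()] (warns, not errors, when empty).
#' @export
filter_sites <- function(g, max_missing = 0.95, maf_min = 0.05,
                         hwe_p_min = 0.001) {
  stopifnot(inherits(g, "geno_matrix"))
  if (ncol(g$codes) == 0) return(g)
  called <- colMeans(!is.na(g$codes))
  p_alt <- colMeans(g$codes + 1, na.rm = TRUE) / 2
  maf <- pmin(p_alt, 1 - p_alt)
  cnt <- locus_counts(g$codes)
  hwe <- vapply(seq_along(cnt$aa), function(j)
    hwe_exact_p(cnt$aa[j], cnt$ab[j], cnt$bb[j]), numeric(1))
  keep <- which(called >= max_missing & maf >= maf_min & hwe >= hwe_p_min)
  if (!length(keep)) warning("filter_sites removed every locus")
  subset_geno(g, loci = keep)
}

#' Drop samples with excessive missingness
#'
#' @param g a [geno_matrix()].
#' @param max_sample_missing samples with a missing fraction strictly above
#'   this threshold are dropped (default 0.65).
#' @return filtered [geno_matrix()].
#' @export
filter_samples <- function(g, max_sample_missing = 0.65) {
  stopifnot(inherits(g, "geno_matrix"))
  miss <- rowMeans(is.na(g$codes))
  keep <- which(miss <= max_sample_missing)
  if (!length(keep)) warning("filter_samples removed every sample")
  subset_geno(g, samples = keep)
}

#' Remove scaffolds' solitary SNPs
#'
#' A scaffold contributing exactly one SNP has that SNP removed.
#'
#' @param g a [geno_matrix()].
#' @return filtered [geno_matrix()].
#' @export
remove_solitary_snps <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  if (ncol(g$codes) == 0) return(g)
  counts <- table(g$loci$scaffold)
  keep <- which(g$loci$scaffold %in% names(counts)[counts >= 2])
  subset_geno(g, loci = keep)
}

#' Thin loci to a minimum within-scaffold spacing
#'
#' Greedy left-to-right rule per scaffold: a locus is kept iff it lies at
#' least `min_bp` from the last kept locus (VCFtools `--thin` behaviour).
#'
#' @param g a [geno_matrix()] (loci are kept sorted by scaffold, position).
#' @param min_bp minimum spacing in bp (default 1000).
#' @return thinned [geno_matrix()].
#' @export
thin_by_distance <- function(g, min_bp = 1000) {
  stopifnot(inherits(g, "geno_matrix"))
  if (ncol(g$codes) == 0) return(g)
  keep <- logical(nrow(g$loci))
  for (sc in unique(g$loci$scaffold)) {
    idx <- which(g$loci$scaffold == sc)
    last <- -Inf
    for (i in idx) {
      if (g$loci$pos[i] - last >= min_bp) {
        keep[i] <- TRUE
        last <- g$loci$pos[i]
      }
    }
  }
  subset_geno(g, loci = which(keep))
}

#' Impute missing genotype codes
#'
#' Stand-in for haplotype-based imputation: replaces missing codes by the
#' per-locus mean (continuous codes) or mode (categorical codes). The phase
#' layer is dropped when any genotype had to be imputed.
#'
#' @param g a [geno_matrix()].
#' @param method `"mean"` or `"mode"`.
#' @return completed [geno_matrix()] without missing values.
#' @export
impute_missing <- function(g, method = c("mean", "mode")) {
  stopifnot(inherits(g, "geno_matrix"))
  method <- match.arg(method)
  codes <- g$codes
  all_missing <- colSums(!is.na(codes)) == 0
  if (any(all_missing)) stop("locus with all genotypes missing cannot be imputed")
  any_missing <- anyNA(codes)
  if (any_missing) {
    for (j in which(colSums(is.na(codes)) > 0)) {
      miss <- is.na(codes[, j])
      fill <- if (method == "mean") mean(codes[, j], na.rm = TRUE) else {
        tab <- table(factor(codes[!miss, j], levels = c(-1, 0, 1)))
        as.numeric(names(tab)[which.max(tab)])
      }
      codes[miss, j] <- fill
    }
  }
  phase <- if (any_missing) NULL else g$phase
  geno_matrix(codes, g$loci, phase)
}

#' Principal component analysis of the genotype matrix
#'
#' Centered (not scaled) PCA via singular-value decomposition.
#'
#' @param g a [geno_matrix()] without missing codes.
#' @param n_pcs number of components to return (default all).
#' @return list with `coordinates` (sample scores), `var_explained_pct`
#'   (percent variance per component, non-increasing) and `sdev`.
#' @export
genotype_pca <- function(g, n_pcs = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  if (nrow(g$codes) < 2) stop("PCA requires at least 2 samples")
  if (anyNA(g$codes)) stop("impute missing genotypes before PCA")
  pr <- prcomp(g$codes, center = TRUE, scale. = FALSE)
  ve <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  k <- if (is.null(n_pcs)) length(pr$sdev) else min(n_pcs, length(pr$sdev))
  list(coordinates = pr$x[, seq_len(k), drop = FALSE],
       var_explained_pct = ve[seq_len(k)], sdev = pr$sdev[seq_len(k)])
}

#' Within-scaffold pairwise linkage disequilibrium
#'
#' r2 is the squared Pearson correlation of the coded genotype vectors
#' (composite LD on unphased codes). All within-scaffold pairs are computed;
#' scaffolds exceeding `max_pairs_per_scaffold` pairs are subsampled using
#' the current RNG state. Monomorphic loci are skipped with a reported count.
#'
#' @param g a [geno_matrix()] without missing codes.
#' @param max_pairs_per_scaffold cap on pairs per scaffold (default all).
#' @return data.frame with columns `scaffold`, `dist` (bp) and `r2`.
#' @export
pairwise_ld <- function(g, max_pairs_per_scaffold = Inf) {
  stopifnot(inherits(g, "geno_matrix"))
  if (anyNA(g$codes)) stop("impute missing genotypes before LD computation")
  res <- list()
  n_mono <- 0L
  for (sc in unique(g$loci$scaffold)) {
    idx <- which(g$loci$scaffold == sc)
    poly <- idx[apply(g$codes[, idx, drop = FALSE], 2, sd) > 0]
    n_mono <- n_mono + length(idx) - length(poly)
    if (length(poly) < 2) next
    C <- cor(g$codes[, poly, drop = FALSE])^2
    ut <- which(upper.tri(C), arr.ind = TRUE)
    if (nrow(ut) > max_pairs_per_scaffold)
      ut <- ut[sample.int(nrow(ut), max_pairs_per_scaffold), , drop = FALSE]
    res[[sc]] <- data.frame(
      scaffold = sc,
      dist = abs(g$loci$pos[poly[ut[, 2]]] - g$loci$pos[poly[ut[, 1]]]),
      r2 = C[ut], stringsAsFactors = FALSE)
  }
  if (n_mono > 0)
    message(sprintf("pairwise_ld: skipped %d monomorphic locus/loci", n_mono))
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(scaffold = character(0),
                                      dist = numeric(0), r2 = numeric(0))
  rownames(out) <- NULL
  out
}

#' Linkage-disequilibrium decay distance from a loess trend
#'
#' Fits a local quadratic regression of r2 on inter-locus distance, choosing
#' the span over a fixed grid by 4-fold cross-validation minimizing RMSE
#' (folds interleaved along the distance ordering for determinism), and
#' reports the smallest distance at which the fitted curve first crosses
#' `r2_cut` from above.
#'
#' @param ld data.frame from [pairwise_ld()] (needs `dist`, `r2`).
#' @param r2_cut crossing threshold (default 0.1).
#' @param spans candidate loess spans.
#' @return list with `decay_bp` (NA if the curve never crosses), `span`,
#'   `cv_rmse` and `curve` (fitted trend on a fine grid).
#' @export
ld_decay <- function(ld, r2_cut = 0.1, spans = seq(0.1, 1, by = 0.1)) {
  if (nrow(ld) < 20) stop("fewer than 20 LD pairs: decay fit unreliable")
  ord <- order(ld$dist)
  fold <- integer(nrow(ld))
  fold[ord] <- rep_len(1:4, nrow(ld))
  cv <- vapply(spans, function(sp) {
    errs <- vapply(1:4, function(f) {
      tr <- ld[fold != f, ]; te <- ld[fold == f, ]
      fit <- tryCatch(suppressWarnings(
        loess(r2 ~ dist, data = tr, span = sp, degree = 2,
              control = loess.control(surface = "interpolate"))),
        error = function(e) NULL)
      if (is.null(fit)) return(Inf)
      pred <- tryCatch(suppressWarnings(predict(fit, newdata = te)),
                       error = function(e) rep(NA_real_, nrow(te)))
      ok <- !is.na(pred)
      if (!any(ok)) return(Inf)
      sqrt(mean((pred[ok] - te$r2[ok])^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  span <- spans[which.min(cv)]
  fit <- suppressWarnings(
    loess(r2 ~ dist, data = ld, span = span, degree = 2,
          control = loess.control(surface = "interpolate")))
  grid <- seq(min(ld$dist), max(ld$dist), length.out = 2000)
  pred <- suppressWarnings(predict(fit, newdata = data.frame(dist = grid)))
  decay <- NA_real_
  if (!all(is.na(pred))) {
    if (pred[1] <= r2_cut) {
      decay <- grid[1]
    } else {
      below <- which(pred[-1] <= r2_cut & pred[-length(pred)] > r2_cut)
      if (length(below)) {
        i <- below[1]
        # linear interpolation between grid points i and i+1
        decay <- unname(grid[i] + (grid[i + 1] - grid[i]) *
                          (pred[i] - r2_cut) / (pred[i] - pred[i + 1]))
      }
    }
  }
  list(decay_bp = decay, span = span, cv_rmse = setNames(cv, spans),
       curve = data.frame(dist = grid, r2_fit = as.numeric(pred)))
}

#' Genome size and marker coverage from a C-value
#'
#' Genome size (bp) = C-value (pg) x 0.978e9; approximate genomic coverage of
#' the marker panel = LD-decay distance x number of thinned SNPs / genome
#' size.
#'
#' @param c_value_pg haploid genome C-value in picograms.
#' @param decay_bp LD-decay distance in bp.
#' @param n_thinned_snps number of SNPs after distance thinning.
#' @return list with `genome_bp`, `coverage_fraction` and `coverage_pct`.
#' @export
estimate_genome_coverage <- function(c_value_pg, decay_bp, n_thinned_snps) {
  stopifnot(c_value_pg > 0, decay_bp > 0, n_thinned_snps > 0)
  genome_bp <- c_value_pg * 0.978e9
  frac <- decay_bp * n_thinned_snps / genome_bp
  list(genome_bp = genome_bp, coverage_fraction = frac,
       coverage_pct = 100 * frac)
}
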