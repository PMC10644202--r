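# shared fixture builders: everything is generated in code at test time

tiny_config <- function(seed = 1, ...) {
  args <- modifyList(list(
    n_mothers = 20, progeny_per_family_per_block = 2, n_blocks = 4,
    n_founder_haplotypes = 80, n_scaffolds = 20, snps_per_scaffold = 12,
    scaffold_length_bp = 30000, ld_decay_bp = 2000,
    phenotype_missing_rate = 0.2, seed = seed), list(...))
  do.call(sim_config, args)
}

# simple unstructured genotype matrix (independent loci)
random_geno <- function(n, m, p = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(p)) p <- runif(m, 0.1, 0.5)
  X <- sapply(p, function(pj) rbinom(n, 2, pj) - 1)
  rownames(X) <- sprintf("s%03d", seq_len(n))
  colnames(X) <- sprintf("snp%04d", seq_len(m))
  X
}

# two diverged founder pools -> strong population structure
two_pool_geno <- function(n_per = 60, m = 200, fst_shift = 0.25, seed = 1) {
  set.seed(seed)
  p0 <- runif(m, 0.2, 0.8)
  p1 <- pmin(pmax(p0 + fst_shift * sample(c(-1, 1), m, TRUE), 0.05), 0.95)
  p2 <- pmin(pmax(p0 - fst_shift * sample(c(-1, 1), m, TRUE), 0.05), 0.95)
  X <- rbind(sapply(p1, function(p) rbinom(n_per, 2, p) - 1),
             sapply(p2, function(p) rbinom(n_per, 2, p) - 1))
  rownames(X) <- sprintf("s%03d", seq_len(2 * n_per))
  colnames(X) <- sprintf("snp%04d", seq_len(m))
  list(X = X, pool = rep(1:2, each = n_per))
}

# geno_matrix wrapper around a plain matrix with evenly spaced loci
as_geno <- function(X, n_scaffolds = 1, spacing = 500) {
  m <- ncol(X)
  per <- ceiling(m / n_scaffolds)
  scaffold <- sprintf("sc%02d", rep(seq_len(n_scaffolds), each = per))[1:m]
  pos <- rep(seq_len(per) * spacing, n_scaffolds)[1:m]
  geno_matrix(X, data.frame(scaffold = scaffold, pos = pos))
}

# genomic-control inflation factor from scan p-values
inflation_factor <- function(p) {
  p <- p[!is.na(p)]
  median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
}

write_tiny_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
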