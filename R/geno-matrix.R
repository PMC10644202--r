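#' Genotype matrix container
#'
#' Holds biallelic SNP genotypes coded -1 (homozygous reference),
#' 0 (heterozygous), 1 (homozygous alternative), with per-locus scaffold and
#' position metadata and an optional phase layer (two binary gamete layers,
#' reference allele = 0, alternative allele = 1).
#'
#' @param codes numeric sample x locus matrix with values in \[-1, 1\] or NA.
#'   Fractional values are permitted after mean imputation.
#' @param loci data.frame with columns `id`, `scaffold`, `pos`, and optionally
#'   `ref`, `alt`. Loci must be sortable by (scaffold, pos).
#' @param phase optional sample x locus x 2 binary array; for every called
#'   genotype the two phase entries must sum to `code + 1`.
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(codes, loci, phase = NULL) {
  codes <- as.matrix(codes)
  stopifnot(is.data.frame(loci), all(c("scaffold", "pos") %in% names(loci)))
  if (is.null(loci$id)) loci$id <- paste0(loci$scaffold, "_", loci$pos)
  if (ncol(codes) != nrow(loci)) stop("codes/loci dimension mismatch")
  if (anyDuplicated(loci[, c("scaffold", "pos")]))
    stop("two loci at identical scaffold/position are not allowed")
  if (length(codes) && !all(is.na(codes))) {
    rng <- range(codes, na.rm = TRUE)
    if (rng[1] < -1 - 1e-8 || rng[2] > 1 + 1e-8)
      stop("genotype codes must lie in [-1, 1]")
  }
  ord <- order(loci$scaffold, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  codes <- codes[, ord, drop = FALSE]
  colnames(codes) <- loci$id
  if (is.null(rownames(codes))) rownames(codes) <- paste0("s", seq_len(nrow(codes)))
  if (!is.null(phase)) {
    stopifnot(length(dim(phase)) == 3L, dim(phase)[3] == 2L)
    phase <- phase[, ord, , drop = FALSE]
    chk <- phase[, , 1] + phase[, , 2] - 1
    ok <- is.na(codes) | abs(chk - codes) < 1e-8
    if (!all(ok)) stop("phase layers inconsistent with genotype codes")
  }
  structure(list(codes = codes, loci = loci, phase = phase,
                 samples = rownames(codes)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d loci on %d scaffolds%s\n",
              nrow(x$codes), ncol(x$codes), length(unique(x$loci$scaffold)),
              if (!is.null(x$phase)) " (phased)" else ""))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$codes)

# subset helper keeping metadata in sync
subset_geno <- function(g, samples = NULL, loci = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(g$codes))
  if (is.null(loci)) loci <- seq_len(ncol(g$codes))
  phase <- if (!is.null(g$phase)) g$phase[samples, loci, , drop = FALSE]
  geno_matrix(g$codes[samples, loci, drop = FALSE],
              g$loci[loci, , drop = FALSE], phase)
}
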