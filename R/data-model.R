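#' @keywords internal
"_PACKAGE"

#' Construct a SNP data set
#'
#' The canonical in-memory container used throughout the pipeline: a variant
#' table plus a samples-by-variants dosage matrix, with optional per-call
#' depth/quality matrices and phased haplotypes.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based bp),
#'   `ref`, `alt`, and optionally `qual` (variant-level allele quality,
#'   phred) and `stage_flags` (semicolon-separated filter-stage labels).
#' @param dosage integer matrix, samples x variants, values 0/1/2 or `NA`
#'   for a missing call. Row names are accession IDs.
#' @param dp,gq optional numeric matrices of per-call read depth and
#'   genotype quality, same shape as `dosage`.
#' @param phased optional 0/1 matrix of haplotypes, `2 * nsamples` rows
#'   (rows `2i - 1` and `2i` are the two haplotypes of sample `i`); each
#'   haplotype pair must sum to the non-missing dosage.
#' @return An object of class `snp_data`.
#' @export
snp_data <- function(variants, dosage, dp = NULL, gq = NULL, phased = NULL) {
  stopifnot(is.data.frame(variants), is.matrix(dosage))
  if (nrow(variants) != ncol(dosage)) {
    stop("dimension mismatch: ", nrow(variants), " variants vs ",
         ncol(dosage), " dosage columns")
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  }
  if (!"stage_flags" %in% names(variants)) {
    variants$stage_flags <- character(nrow(variants))
  }
  o <- order(variants$chrom, variants$pos)
  if (is.unsorted(o)) {
    variants <- variants[o, , drop = FALSE]
    dosage   <- dosage[, o, drop = FALSE]
    if (!is.null(dp)) dp <- dp[, o, drop = FALSE]
    if (!is.null(gq)) gq <- gq[, o, drop = FALSE]
    if (!is.null(phased)) phased <- phased[, o, drop = FALSE]
  }
  rownames(variants) <- NULL
  x <- structure(list(variants = variants, dosage = dosage,
                      dp = dp, gq = gq, phased = phased),
                 class = "snp_data")
  validate_snp_data(x)
  x
}

validate_snp_data <- function(x) {
  v <- x$variants
  if (any(v$pos < 1)) stop("positions must be >= 1")
  if (any(v$ref == v$alt)) stop("ref and alt alleles must differ")
  if (!is.null(x$phased)) {
    if (nrow(x$phased) != 2L * nrow(x$dosage)) {
      stop("phased matrix must have 2 rows per sample")
    }
    ds <- x$phased[seq(1, nrow(x$phased), 2), , drop = FALSE] +
          x$phased[seq(2, nrow(x$phased), 2), , drop = FALSE]
    ok <- is.na(x$dosage) | ds == x$dosage
    if (!all(ok)) stop("haplotype pair sums disagree with dosages")
  }
  invisible(x)
}

#' @export
print.snp_data <- function(x, ...) {
  cat("snp_data:", nrow(x$dosage), "samples x", nrow(x$variants),
      "variants;", if (is.null(x$phased)) "unphased" else "phased",
      "\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "),
      "\n")
  cat("  missing calls:",
      sprintf("%.2f%%", 100 * mean(is.na(x$dosage))), "\n")
  invisible(x)
}

#' Number of samples / variants in a `snp_data` object
#' @param x a `snp_data` object
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$dosage)

#' @rdname n_samples
#' @export
n_variants <- function(x) nrow(x$variants)

#' Subset a SNP data set
#'
#' @param x a `snp_data` object.
#' @param samples sample index/name vector (optional).
#' @param variants variant index vector (optional).
#' @return A `snp_data` subset, with phase rows kept in step.
#' @export
subset_snp <- function(x, samples = NULL, variants = NULL) {
  if (is.null(samples)) samples <- seq_len(n_samples(x))
  if (is.character(samples)) samples <- match(samples, rownames(x$dosage))
  if (anyNA(samples)) stop("unknown sample in subset")
  if (is.null(variants)) variants <- seq_len(n_variants(x))
  hap_rows <- as.vector(rbind(2L * samples - 1L, 2L * samples))
  structure(list(
    variants = {v <- x$variants[variants, , drop = FALSE]; rownames(v) <- NULL; v},
    dosage   = x$dosage[samples, variants, drop = FALSE],
    dp       = if (!is.null(x$dp)) x$dp[samples, variants, drop = FALSE],
    gq       = if (!is.null(x$gq)) x$gq[samples, variants, drop = FALSE],
    phased   = if (!is.null(x$phased)) x$phased[hap_rows, variants, drop = FALSE]
  ), class = "snp_data")
}

#' Per-variant call rate
#' @param x a `snp_data` object.
#' @return numeric vector in \[0, 1\], one entry per variant.
#' @export
call_rate <- function(x) colMeans(!is.na(x$dosage))

#' Per-variant ALT allele frequency (missing calls excluded)
#' @param x a `snp_data` object.
#' @return numeric vector of ALT frequencies.
#' @export
alt_freq <- function(x) colMeans(x$dosage, na.rm = TRUE) / 2

#' Append a filter-stage flag to a set of variants
#' @param variants a variant data.frame.
#' @param idx indices of the variants that passed the stage.
#' @param flag stage label, e.g. "qc_pass".
#' @return The variant table with `stage_flags` extended.
#' @export
add_stage_flag <- function(variants, idx, flag) {
  cur <- variants$stage_flags[idx]
  variants$stage_flags[idx] <- ifelse(cur == "", flag,
                                      paste(cur, flag, sep = ";"))
  variants
}

## Round half-up to `digits` decimals (base round() is half-to-even; the
## funnel and report tables print conventional half-up percentages).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Render a percentage the way the report tables print it
#'
#' Half-up rounding to a fixed number of decimals, with a trailing percent
#' sign: `pct(61924, 173925)` is `"35.61%"`.
#'
#' @param count numerator.
#' @param total denominator.
#' @param digits decimal places (default 2).
#' @return character vector like "35.61%".
#' @export
pct <- function(count, total, digits = 2) {
  sprintf(paste0("%.", digits, "f%%"),
          round_half_up(100 * count / total, digits))
}
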