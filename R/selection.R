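#' Minor-allele-frequency filter
#'
#' Removes variants with pooled MAF strictly below `min_maf` (so a
#' variant at exactly the threshold is kept). Frequencies are estimated
#' by allele counting with missing calls excluded.
#'
#' @param x a `snp_data` object.
#' @param min_maf threshold (default 0.05).
#' @param samples optional subset of samples to estimate frequencies on.
#' @return logical keep vector over variants.
#' @export
maf_filter <- function(x, min_maf = 0.05, samples = NULL) {
  D <- x$dosage
  if (!is.null(samples)) D <- D[samples, , drop = FALSE]
  p <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  !is.na(maf) & maf >= min_maf
}

#' Two-population sliding-window differentiation scan
#'
#' Per-SNP statistic `d = (p1 - p2)^2 / (pbar (1 - pbar))` with `pbar`
#' the pooled allele frequency — a symmetric allele-frequency-
#' differentiation score standing in for a composite-likelihood sweep
#' statistic; the windowing protocol (window/step/minimum SNP count) is
#' the scan's contract and any per-SNP statistic can be plugged in.
#' Windows with fewer than `min_snps` SNPs carry no score.
#'
#' @param x a `snp_data` object (MAF-filtered).
#' @param pop_a,pop_b sample index or name vectors (>= 2 samples each).
#' @param window,step window and step size in bp (defaults 50 kb / 10 kb).
#' @param min_snps minimum SNPs per scored window (default 5).
#' @param statistic function(p1, p2, pbar) -> per-SNP score; default the
#'   normalized squared frequency difference.
#' @return data.frame of class `window_scores`: chrom, start, end, mid,
#'   n_snps, score (NA when unscored), percentile (rank over scored
#'   windows).
#' @export
window_scan <- function(x, pop_a, pop_b, window = 50000, step = 10000,
                        min_snps = 5, statistic = NULL) {
  if (is.character(pop_a)) pop_a <- match(pop_a, rownames(x$dosage))
  if (is.character(pop_b)) pop_b <- match(pop_b, rownames(x$dosage))
  if (length(pop_a) < 2 || length(pop_b) < 2) {
    stop("each population needs >= 2 samples")
  }
  if (is.null(statistic)) {
    statistic <- function(p1, p2, pbar) (p1 - p2)^2 / (pbar * (1 - pbar))
  }
  Da <- x$dosage[pop_a, , drop = FALSE]
  Db <- x$dosage[pop_b, , drop = FALSE]
  p1 <- colMeans(Da, na.rm = TRUE) / 2
  p2 <- colMeans(Db, na.rm = TRUE) / 2
  n1 <- colSums(!is.na(Da)); n2 <- colSums(!is.na(Db))
  pbar <- (colSums(Da, na.rm = TRUE) + colSums(Db, na.rm = TRUE)) /
    (2 * (n1 + n2))
  d <- statistic(p1, p2, pbar)
  d[!is.finite(d)] <- NA  # monomorphic pooled sites carry no information
  v <- x$variants
  out <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    pos <- v$pos[idx]
    max_pos <- max(pos)
    starts <- seq(1L, max(1L, max_pos), by = step)
    for (s in starts) {
      e <- s + window - 1L
      inw <- idx[pos >= s & pos <= e]
      dw <- d[inw]
      dw <- dw[!is.na(dw)]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = e, mid = (s + e) / 2,
        n_snps = length(dw),
        score = if (length(dw) >= min_snps) mean(dw) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  scored <- !is.na(res$score)
  res$percentile <- NA_real_
  res$percentile[scored] <- rank(res$score[scored]) / sum(scored)
  rownames(res) <- NULL
  class(res) <- c("window_scores", "data.frame")
  res
}

#' Candidate selective regions from the top-scoring windows
#'
#' Keeps the top `top_fraction` of scored windows — the score threshold
#' is the value of the `floor(top_fraction * n)`-th window from the top
#' (at least one), ties included — and merges overlapping or adjacent
#' kept windows into regions.
#'
#' @param scores [window_scan()] output.
#' @param top_fraction fraction of scored windows to keep (default
#'   0.01).
#' @return data.frame: chrom, start, end, max_score, n_windows,
#'   threshold.
#' @export
top_regions <- function(scores, top_fraction = 0.01) {
  sc <- scores[!is.na(scores$score), , drop = FALSE]
  if (!nrow(sc)) stop("no scored windows")
  k <- max(1L, floor(top_fraction * nrow(sc)))
  thr <- sort(sc$score, decreasing = TRUE)[k]
  keep <- sc[sc$score >= thr, , drop = FALSE]
  out <- lapply(split(keep, keep$chrom), function(kk) {
    kk <- kk[order(kk$start), , drop = FALSE]
    grp <- cumsum(c(1L, kk$start[-1] > kk$end[-nrow(kk)] + 1L))
    do.call(rbind, lapply(split(kk, grp), function(g) {
      data.frame(chrom = g$chrom[1], start = min(g$start),
                 end = max(g$end), max_score = max(g$score),
                 n_windows = nrow(g), threshold = thr,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
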