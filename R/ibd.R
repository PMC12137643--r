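## Convert a logical identity vector over the marker map into segments,
## chromosome by chromosome, allowing up to `g` interior mismatches per
## run. Runs are trimmed to matching markers at both ends and kept if they
## span >= min_markers markers and >= min_bp bases.
runs_to_segments <- function(eq, variants, min_markers, min_bp, g = 0) {
  out <- list()
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    e <- eq[idx]
    e[is.na(e)] <- FALSE
    len <- length(e)
    if (!len) next
    bad <- which(!e)
    # pad the right sentinel so the formula also covers runs with fewer
    # than g interior mismatches (e.g. a fully identical chromosome)
    bounds <- c(0L, bad, rep(len + 1L, g + 1L))
    nb <- length(bad)
    # window i spans (bounds[i], bounds[i + g + 1]) exclusive: <= g FALSEs
    n_win <- nb + 1L
    seen <- character(0)
    for (i in seq_len(max(n_win, 0))) {
      lo <- bounds[i] + 1L
      hi <- bounds[i + g + 1L] - 1L
      if (lo > hi) next
      while (lo <= hi && !e[lo]) lo <- lo + 1L
      while (hi >= lo && !e[hi]) hi <- hi - 1L
      if (lo > hi) next
      key <- paste(lo, hi)
      if (key %in% seen) next
      seen <- c(seen, key)
      n_mark <- hi - lo + 1L
      start <- variants$pos[idx[lo]]
      end <- variants$pos[idx[hi]]
      if (n_mark >= min_markers && (end - start + 1) >= min_bp) {
        out[[length(out) + 1L]] <- data.frame(
          sample_a = NA_character_, sample_b = NA_character_,
          chrom = ch, start = start, end = end,
          score = n_mark, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample_a = character(), sample_b = character(),
                      chrom = character(), start = integer(),
                      end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Call IBD segments from phased haplotypes (IBS-run stand-in)
#'
#' A deliberately simple substitute for an HMM-based detector: for each
#' sample pair and each of the four haplotype combinations, maximal runs
#' of marker-identical alleles (allowing up to `max_mismatch` interior
#' mismatches) are collected, filtered by physical span and marker count,
#' and unioned per pair. Intended for error-free or low-error data; for
#' real array data supply RefinedIBD output via [read_refined_ibd()]
#' instead.
#'
#' @param x phased `snp_data`.
#' @param min_bp minimum physical span of a run (default 1 Mb).
#' @param min_markers minimum markers per run (default 50).
#' @param max_mismatch interior mismatches tolerated per run (default 1).
#' @param pairs optional 2-column matrix/data.frame of sample names to
#'   restrict to; default all pairs.
#' @return An `ibd_segments` data.frame (sample_a, sample_b, chrom,
#'   start, end, score = supporting marker count).
#' @export
call_ibd_segments <- function(x, min_bp = 1e6, min_markers = 50,
                              max_mismatch = 1, pairs = NULL) {
  if (is.null(x$phased)) {
    stop("phased haplotypes required; for unphased data supply ",
         "RefinedIBD segment files via read_refined_ibd()")
  }
  ids <- rownames(x$dosage)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ids, 2))
  }
  v <- x$variants
  segs <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- match(pairs[r, 1], ids); b <- match(pairs[r, 2], ids)
    if (is.na(a) || is.na(b) || a == b) stop("bad pair at row ", r)
    pair_segs <- list()
    for (ha in c(2 * a - 1, 2 * a)) {
      for (hb in c(2 * b - 1, 2 * b)) {
        eq <- x$phased[ha, ] == x$phased[hb, ]
        s <- runs_to_segments(eq, v, min_markers, min_bp, g = max_mismatch)
        if (nrow(s)) pair_segs[[length(pair_segs) + 1L]] <- s
      }
    }
    if (length(pair_segs)) {
      s <- do.call(rbind, pair_segs)
      nm <- sort(c(ids[a], ids[b]))
      s$sample_a <- nm[1]; s$sample_b <- nm[2]
      segs[[length(segs) + 1L]] <- s
    }
  }
  if (!length(segs)) {
    return(merge_pair_segments(data.frame(
      sample_a = character(), sample_b = character(), chrom = character(),
      start = integer(), end = integer(), score = numeric())))
  }
  merge_pair_segments(do.call(rbind, segs))
}

#' Per-bin pair-coverage pileup of IBD segments within a cluster
#'
#' Restricts segments to pairs with both members in the cluster and, for
#' each genomic bin, counts the distinct within-cluster pairs whose
#' segment covers the bin midpoint.
#'
#' @param segments an `ibd_segments` data.frame.
#' @param cluster_members character vector of member IDs (>= 2).
#' @param bin_bp bin width (default 10 kb).
#' @param chrom_lengths optional named lengths; defaults to the largest
#'   segment end per chromosome.
#' @return data.frame (chrom, bin_start, bin_end, mid, count) of class
#'   `ibd_pileup`; all bins are emitted, including zero-count ones.
#' @export
ibd_pileup <- function(segments, cluster_members, bin_bp = 10000,
                       chrom_lengths = NULL) {
  if (length(cluster_members) < 2) stop("cluster must have >= 2 members")
  seg <- segments[segments$sample_a %in% cluster_members &
                  segments$sample_b %in% cluster_members, , drop = FALSE]
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths) else
    unique(seg$chrom)
  out <- lapply(chroms, function(ch) {
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else {
      s <- seg[seg$chrom == ch, ]
      if (!nrow(s)) return(NULL)
      max(s$end)
    }
    n_bin <- ceiling(L / bin_bp)
    bin_start <- (seq_len(n_bin) - 1L) * bin_bp + 1L
    bin_end <- pmin(bin_start + bin_bp - 1L, L)
    mid <- (bin_start + bin_end) / 2
    count <- integer(n_bin)
    s <- seg[seg$chrom == ch, , drop = FALSE]
    if (nrow(s)) {
      pair_key <- paste(s$sample_a, s$sample_b)
      for (b in seq_len(n_bin)) {
        cov <- s$start <= mid[b] & s$end >= mid[b]
        count[b] <- length(unique(pair_key[cov]))
      }
    }
    data.frame(chrom = ch, bin_start = bin_start, bin_end = bin_end,
               mid = mid, count = count, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(chrom = character(),
                                      bin_start = integer(),
                                      bin_end = integer(), mid = numeric(),
                                      count = integer())
  class(out) <- c("ibd_pileup", "data.frame")
  out
}

## Lower nearest-rank quantile: value at position ceiling(q * n) of the
## ascending sort (deterministic, no interpolation).
nearest_rank <- function(x, q) {
  s <- sort(x)
  idx <- max(1L, min(length(s), ceiling(q * length(s))))
  s[idx]
}

#' Shared IBD regions: top decile of the pair-coverage pileup
#'
#' The frequency threshold is the `(1 - top_fraction)` lower nearest-rank
#' quantile of the positive bin counts; bins at or above it are kept and
#' adjacent kept bins are merged into regions.
#'
#' @param pileup output of [ibd_pileup()].
#' @param top_fraction fraction of the positive-count distribution to
#'   keep (default 0.10).
#' @param cluster_id optional label carried into the output.
#' @return data.frame (cluster, chrom, start, end, max_count, threshold).
#' @export
shared_regions <- function(pileup, top_fraction = 0.10, cluster_id = NA) {
  pos <- pileup$count[pileup$count > 0]
  if (!length(pos)) {
    return(data.frame(cluster = character(), chrom = character(),
                      start = integer(), end = integer(),
                      max_count = integer(), threshold = numeric()))
  }
  thr <- if (top_fraction >= 1) min(pos) else
    nearest_rank(pos, 1 - top_fraction)
  keep <- pileup[pileup$count >= thr & pileup$count > 0, , drop = FALSE]
  out <- lapply(split(keep, keep$chrom), function(k) {
    k <- k[order(k$bin_start), , drop = FALSE]
    grp <- cumsum(c(1L, diff(k$bin_start) > (k$bin_end[-nrow(k)] -
                                             k$bin_start[-nrow(k)] + 1L)))
    do.call(rbind, lapply(split(k, grp), function(g) {
      data.frame(cluster = cluster_id, chrom = g$chrom[1],
                 start = min(g$bin_start), end = max(g$bin_end),
                 max_count = max(g$count), threshold = thr,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap table between shared IBD regions and candidate intervals
#'
#' @param regions data.frame with `chrom`, `start`, `end` (e.g.
#'   [shared_regions()] output).
#' @param intervals data.frame with `chrom`, `start`, `end` and
#'   optionally `name`.
#' @return data.frame of overlapping (region, interval) pairs with
#'   overlap length in bp and Jaccard index; zero-overlap pairs omitted.
#' @export
overlap_loci <- function(regions, intervals) {
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(intervals))) {
      if (regions$chrom[i] != intervals$chrom[j]) next
      ov <- min(regions$end[i], intervals$end[j]) -
            max(regions$start[i], intervals$start[j]) + 1
      if (ov <= 0) next
      un <- max(regions$end[i], intervals$end[j]) -
            min(regions$start[i], intervals$start[j]) + 1
      rows[[length(rows) + 1L]] <- data.frame(
        region_chrom = regions$chrom[i], region_start = regions$start[i],
        region_end = regions$end[i],
        interval = if ("name" %in% names(intervals))
          intervals$name[j] else paste0(intervals$chrom[j], ":",
                                        intervals$start[j], "-",
                                        intervals$end[j]),
        overlap_bp = ov, jaccard = ov / un, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(region_chrom = character(), region_start = integer(),
                      region_end = integer(), interval = character(),
                      overlap_bp = numeric(), jaccard = numeric()))
  }
  do.call(rbind, rows)
}
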