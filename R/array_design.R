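#' Quality-control filter for candidate array SNPs
#'
#' Keeps variants with missing rate <= `max_missing` (inclusive), mean
#' depth across non-missing calls >= `min_depth`, mean genotype quality
#' >= `min_gq`, and variant-level allele quality (QUAL) >= `min_qual`.
#' A variant missing a required metric fails that criterion (counted in
#' the report). Survivors gain the stage flag `"qc_pass"`.
#'
#' @param x a `snp_data` object with `dp`, `gq` and `variants$qual`.
#' @param max_missing,min_depth,min_gq,min_qual thresholds.
#' @return List: `data` (filtered `snp_data`), `keep` (logical over input
#'   variants), `report` (per-criterion failure counts).
#' @export
qc_filter <- function(x, max_missing = 0.4, min_depth = 2.0,
                      min_gq = 10, min_qual = 50) {
  if (max_missing < 0 || max_missing > 1) stop("max_missing outside [0, 1]")
  if (min_depth < 0 || min_gq < 0 || min_qual < 0) stop("negative threshold")
  miss <- 1 - call_rate(x)
  mean_or_na <- function(M) {
    if (is.null(M)) return(rep(NA_real_, n_variants(x)))
    colMeans(M, na.rm = TRUE)
  }
  dp <- mean_or_na(if (!is.null(x$dp)) {
    d <- x$dp; d[is.na(x$dosage)] <- NA; d
  } else NULL)
  gq <- mean_or_na(if (!is.null(x$gq)) {
    g <- x$gq; g[is.na(x$dosage)] <- NA; g
  } else NULL)
  qual <- if ("qual" %in% names(x$variants)) x$variants$qual else
    rep(NA_real_, n_variants(x))
  ok_miss <- miss <= max_missing
  ok_dp <- !is.na(dp) & dp >= min_depth
  ok_gq <- !is.na(gq) & gq >= min_gq
  ok_qual <- !is.na(qual) & qual >= min_qual
  keep <- ok_miss & ok_dp & ok_gq & ok_qual
  out <- subset_snp(x, variants = which(keep))
  out$variants <- add_stage_flag(out$variants, seq_len(nrow(out$variants)),
                                 "qc_pass")
  list(data = out, keep = keep,
       report = c(fail_missing = sum(!ok_miss), fail_depth = sum(!ok_dp),
                  fail_gq = sum(!ok_gq), fail_qual = sum(!ok_qual),
                  kept = sum(keep)))
}

#' Keep variants whose ALT allele is carried by at least two accessions
#'
#' @param x a `snp_data` object.
#' @param min_carriers minimum accessions with dosage >= 1 (default 2).
#' @return List: `data` (filtered, flag `"shared2"`), `keep` (logical).
#' @export
shared_variant_filter <- function(x, min_carriers = 2) {
  carriers <- colSums(x$dosage >= 1, na.rm = TRUE)
  keep <- carriers >= min_carriers
  out <- subset_snp(x, variants = which(keep))
  out$variants <- add_stage_flag(out$variants, seq_len(nrow(out$variants)),
                                 "shared2")
  list(data = out, keep = keep)
}

#' Probe-uniqueness surrogate filter
#'
#' Deterministic stand-in for an array maker's probe-convertibility score,
#' targeting the same failure mode (sequence repetition): a variant is
#' removed if any k-mer of its probe flank occurs more than `max_hits`
#' times in the reference (either strand), if the flank runs off the
#' contig end, or if another candidate variant lies within the probe
#' window.
#'
#' @param x a `snp_data` object.
#' @param reference a `DNAStringSet` (names = chromosome labels).
#' @param k k-mer length (default 16).
#' @param max_hits maximum allowed genome-wide occurrences per k-mer.
#' @param flank probe half-window in bp (default 35).
#' @param check_neighbors also remove variants with another variant
#'   inside the window (default TRUE).
#' @return List: `data` (filtered, flag `"probe_ok"`), `keep`, `reason`
#'   (character: "", "edge", "repeat", "neighbor").
#' @export
probe_uniqueness_filter <- function(x, reference, k = 16, max_hits = 1,
                                    flank = 35, check_neighbors = TRUE) {
  v <- x$variants
  m <- nrow(v)
  reason <- character(m)
  starts <- v$pos - flank
  ends <- v$pos + flank
  chrom_len <- stats::setNames(Biostrings::width(reference),
                               names(reference))
  edge <- is.na(chrom_len[v$chrom]) | starts < 1 |
    ends > chrom_len[v$chrom]
  reason[edge] <- "edge"
  if (check_neighbors && m > 1) {
    for (ch in unique(v$chrom)) {
      idx <- which(v$chrom == ch)
      pos <- v$pos[idx]
      o <- order(pos)
      gaps_prev <- c(Inf, diff(pos[o]))
      gaps_next <- c(diff(pos[o]), Inf)
      close <- gaps_prev <= flank | gaps_next <= flank
      hit <- idx[o][close]
      reason[hit][reason[hit] == ""] <- "neighbor"
    }
  }
  todo <- which(reason == "")
  if (length(todo)) {
    kmers <- character(0)
    owner <- integer(0)
    for (i in todo) {
      s <- as.character(Biostrings::subseq(reference[[v$chrom[i]]],
                                           starts[i], ends[i]))
      n_k <- nchar(s) - k + 1L
      km <- substring(s, seq_len(n_k), seq_len(n_k) + k - 1L)
      kmers <- c(kmers, km)
      owner <- c(owner, rep(i, n_k))
    }
    q <- Biostrings::DNAStringSet(kmers)
    hits_f <- rowSums(Biostrings::vcountPDict(Biostrings::PDict(q),
                                              reference))
    hits_r <- rowSums(Biostrings::vcountPDict(
      Biostrings::PDict(Biostrings::reverseComplement(q)), reference))
    bad_kmer <- (hits_f + hits_r) > max_hits
    bad_var <- unique(owner[bad_kmer])
    reason[bad_var] <- "repeat"
  }
  keep <- reason == ""
  out <- subset_snp(x, variants = which(keep))
  out$variants <- add_stage_flag(out$variants, seq_len(nrow(out$variants)),
                                 "probe_ok")
  list(data = out, keep = keep, reason = reason)
}

#' Genotype-call performance categories for array SNPs
#'
#' Classifies each variant from called genotypes on a genotyped panel:
#' call rate below `call_rate_min` gives `CallRateBelowThreshold`;
#' monomorphic calls give `MonoHighResolution`; both homozygote classes
#' plus the heterozygote give `PolyHighResolution`; a polymorphic variant
#' with the heterozygote but only one homozygote class gives
#' `NoMinorHom`; anything else (including an empty call set) is `Other`.
#' `OffTargetVariant` is only assigned from an external flag vector.
#'
#' @param x a `snp_data` object (the genotyped evaluation panel).
#' @param call_rate_min threshold for `CallRateBelowThreshold`
#'   (default 0.975; the rule is strict `<`).
#' @param off_target optional logical vector marking externally flagged
#'   cluster-quality failures.
#' @return factor of categories, one per variant.
#' @export
classify_performance <- function(x, call_rate_min = 0.975,
                                 off_target = NULL) {
  lv <- c("PolyHighResolution", "MonoHighResolution", "NoMinorHom",
          "OffTargetVariant", "CallRateBelowThreshold", "Other")
  cr <- call_rate(x)
  m <- n_variants(x)
  out <- character(m)
  for (j in seq_len(m)) {
    if (!is.null(off_target) && isTRUE(off_target[j])) {
      out[j] <- "OffTargetVariant"; next
    }
    d <- x$dosage[, j]
    d <- d[!is.na(d)]
    if (!length(d)) { out[j] <- "Other"; next }
    if (cr[j] < call_rate_min) { out[j] <- "CallRateBelowThreshold"; next }
    has_het <- any(d == 1)
    n_hom_classes <- sum(c(any(d == 0), any(d == 2)))
    if (length(unique(d)) == 1L) {
      out[j] <- "MonoHighResolution"
    } else if (has_het && n_hom_classes == 2L) {
      out[j] <- "PolyHighResolution"
    } else if (has_het && n_hom_classes == 1L) {
      out[j] <- "NoMinorHom"
    } else {
      out[j] <- "Other"  # e.g. two hom classes with no het
    }
  }
  factor(out, levels = lv)
}

#' Final array selection from performance categories
#'
#' Retains the two highest-priority categories (`PolyHighResolution`,
#' `NoMinorHom`); the call-rate rule is already encoded in the
#' categories.
#'
#' @param categories factor from [classify_performance()].
#' @return logical vector of retained variants.
#' @export
select_final <- function(categories) {
  categories %in% c("PolyHighResolution", "NoMinorHom")
}

#' Integrate a legacy array's SNP positions into the final set
#'
#' Union by (chrom, pos): `merged = |final| + |legacy| - |overlap|`.
#' Duplicate positions within either input are deduplicated with a
#' warning.
#'
#' @param final_positions,legacy_positions data.frames with `chrom`,
#'   `pos`.
#' @return List: `merged` (positions data.frame), `n_final`, `n_legacy`,
#'   `n_overlap`, `n_merged`.
#' @export
integrate_legacy <- function(final_positions, legacy_positions) {
  dedupe <- function(d, label) {
    key <- paste(d$chrom, d$pos)
    if (anyDuplicated(key)) {
      warning("duplicate positions in ", label, " deduplicated")
      d <- d[!duplicated(key), , drop = FALSE]
    }
    d
  }
  f <- dedupe(final_positions, "final set")
  l <- dedupe(legacy_positions, "legacy set")
  fk <- paste(f$chrom, f$pos)
  lk <- paste(l$chrom, l$pos)
  overlap <- sum(lk %in% fk)
  merged <- rbind(f[, c("chrom", "pos")], l[!lk %in% fk, c("chrom", "pos")])
  merged <- merged[order(merged$chrom, merged$pos), , drop = FALSE]
  rownames(merged) <- NULL
  list(merged = merged, n_final = nrow(f), n_legacy = nrow(l),
       n_overlap = overlap, n_merged = nrow(merged))
}

#' Classify SNP positions relative to gene models
#'
#' Categories: `genic` (inside a gene span, taking precedence),
#' `upstream` / `downstream` (within `flank_bp` of a gene on its
#' strand-oriented 5'/3' side), `upstream/downstream` (in both flank
#' classes of different genes), `intergenic` otherwise. Chromosomes
#' absent from the annotation give `intergenic` with a warning.
#'
#' @param variants data.frame with `chrom`, `pos`.
#' @param annotation a `gene_annotation` from [read_gff()].
#' @param flank_bp flank width (default 1000).
#' @return factor with one category per variant.
#' @export
annotate_regions <- function(variants, annotation, flank_bp = 1000) {
  g <- annotation$genes
  lv <- c("genic", "upstream", "downstream", "upstream/downstream",
          "intergenic")
  m <- nrow(variants)
  out <- character(m)
  missing_chr <- setdiff(unique(variants$chrom), unique(g$chrom))
  if (length(missing_chr)) {
    warning("chromosome(s) absent from annotation: ",
            paste(missing_chr, collapse = ", "))
  }
  for (i in seq_len(m)) {
    gr <- g[g$chrom == variants$chrom[i], , drop = FALSE]
    pos <- variants$pos[i]
    if (nrow(gr) && any(pos >= gr$start & pos <= gr$end)) {
      out[i] <- "genic"; next
    }
    up <- down <- FALSE
    for (r in seq_len(nrow(gr))) {
      if (gr$strand[r] == "-") {
        u <- pos > gr$end[r] & pos <= gr$end[r] + flank_bp
        d <- pos < gr$start[r] & pos >= gr$start[r] - flank_bp
      } else {
        u <- pos < gr$start[r] & pos >= gr$start[r] - flank_bp
        d <- pos > gr$end[r] & pos <= gr$end[r] + flank_bp
      }
      up <- up || u; down <- down || d
    }
    out[i] <- if (up && down) "upstream/downstream" else if (up)
      "upstream" else if (down) "downstream" else "intergenic"
  }
  factor(out, levels = lv)
}

#' Coding-effect annotation of genic SNPs
#'
#' Splices each mRNA's CDS from the reference (reverse-complemented for
#' minus-strand genes), substitutes the ALT allele in the affected codon,
#' and classifies: `synonymous`, `nonsynonymous`, `stop_gain`,
#' `stop_loss`, or `noncoding_genic` (genic but outside every CDS).
#' mRNAs whose CDS length is not divisible by 3 are skipped (flagged at
#' read time). Non-genic SNPs return `NA`.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param annotation a `gene_annotation` with `seq` loaded.
#' @return character vector of effects.
#' @export
annotate_effects <- function(variants, annotation) {
  if (is.null(annotation$seq)) stop("annotation lacks reference sequence")
  cds <- annotation$cds
  genes <- annotation$genes
  ok_mrna <- annotation$mrna$mrna_id[annotation$mrna$frame_ok]
  out <- rep(NA_character_, nrow(variants))
  spliced_cache <- list()
  get_spliced <- function(mid) {
    if (!is.null(spliced_cache[[mid]])) return(spliced_cache[[mid]])
    seg <- cds[cds$mrna_id == mid, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    pieces <- lapply(seq_len(nrow(seg)), function(i) {
      Biostrings::subseq(annotation$seq[[seg$chrom[i]]],
                         seg$start[i], seg$end[i])
    })
    s <- do.call(Biostrings::xscat, pieces)
    # genomic coordinate of each spliced base, 5'->3' on the plus strand
    coords <- unlist(lapply(seq_len(nrow(seg)), function(i)
      seg$start[i]:seg$end[i]))
    if (seg$strand[1] == "-") {
      s <- Biostrings::reverseComplement(s)
      coords <- rev(coords)
    }
    res <- list(seq = s, coords = coords, strand = seg$strand[1])
    spliced_cache[[mid]] <<- res
    res
  }
  for (i in seq_len(nrow(variants))) {
    pos <- variants$pos[i]; ch <- variants$chrom[i]
    in_gene <- genes$chrom == ch & genes$start <= pos & genes$end >= pos
    if (!any(in_gene)) next
    hit <- cds$chrom == ch & cds$start <= pos & cds$end >= pos &
      cds$mrna_id %in% ok_mrna
    if (!any(hit)) { out[i] <- "noncoding_genic"; next }
    mid <- cds$mrna_id[which(hit)[1]]
    sp <- get_spliced(mid)
    cpos <- which(sp$coords == pos)
    if (!length(cpos)) { out[i] <- "noncoding_genic"; next }
    alt <- variants$alt[i]
    if (sp$strand == "-") {
      alt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(alt)))
    }
    codon_i <- (cpos - 1L) %/% 3L
    off <- (cpos - 1L) %% 3L
    codon_ref <- as.character(Biostrings::subseq(sp$seq, 3 * codon_i + 1,
                                                 3 * codon_i + 3))
    codon_alt <- codon_ref
    substr(codon_alt, off + 1L, off + 1L) <- alt
    aa_ref <- Biostrings::GENETIC_CODE[[codon_ref]]
    aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
    out[i] <- if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "stop_gain"
      else if (aa_ref == "*") "stop_loss"
      else "nonsynonymous"
  }
  out
}

#' Adjacent-interval statistics of SNP positions
#'
#' Gap list between consecutive SNPs per chromosome, with the mean,
#' requested percentiles (lower nearest-rank), and the fraction of SNPs
#' with a neighbor within `within_bp`.
#'
#' @param variants data.frame with `chrom`, `pos`.
#' @param probs percentiles to report.
#' @param within_bp neighbor distance for the coverage fraction.
#' @return List: `gaps` (data.frame chrom, gap), `mean_gap`,
#'   `percentiles`, `frac_with_neighbor`.
#' @export
interval_stats <- function(variants, probs = c(0.5, 0.9),
                           within_bp = 3000) {
  gaps <- do.call(rbind, lapply(split(variants$pos, variants$chrom),
    function(p) {
      p <- sort(p)
      if (length(p) < 2) return(NULL)
      data.frame(gap = diff(p))
    }))
  if (is.null(gaps) || nrow(gaps) == 0) {
    return(list(gaps = data.frame(gap = numeric(0)), mean_gap = NaN,
                percentiles = stats::setNames(rep(NA_real_, length(probs)),
                                              paste0("p", 100 * probs)),
                frac_with_neighbor = NA_real_))
  }
  pr <- vapply(probs, function(q) nearest_rank(gaps$gap, q), 0)
  # fraction of SNPs whose nearest neighbor is within the distance
  frac <- mean(unlist(lapply(split(variants$pos, variants$chrom),
    function(p) {
      p <- sort(p)
      if (length(p) == 1) return(FALSE)
      d <- diff(p)
      pmin(c(Inf, d), c(d, Inf)) <= within_bp
    })))
  list(gaps = gaps, mean_gap = mean(gaps$gap),
       percentiles = stats::setNames(pr, paste0("p", 100 * probs)),
       frac_with_neighbor = frac)
}

#' Concordance between two genotype call sets
#'
#' @param calls_a,calls_b dosage matrices over the same (sample, variant)
#'   grid (same dimensions and order).
#' @return List: `overall` (fraction of jointly non-missing calls that
#'   match), `per_sample`, `missing_a`, `missing_b`.
#' @export
genotype_concordance <- function(calls_a, calls_b) {
  stopifnot(all(dim(calls_a) == dim(calls_b)))
  joint <- !is.na(calls_a) & !is.na(calls_b)
  if (!any(joint)) stop("no jointly non-missing calls")
  match_m <- calls_a == calls_b & joint
  per_sample <- rowSums(match_m, na.rm = TRUE) / rowSums(joint)
  list(overall = sum(match_m, na.rm = TRUE) / sum(joint),
       per_sample = per_sample,
       missing_a = mean(is.na(calls_a)),
       missing_b = mean(is.na(calls_b)))
}

#' Funnel report over the filter cascade
#'
#' @param stage_counts named integer vector of variant counts after each
#'   stage, in execution order.
#' @param final_count denominator for the percentage lines (defaults to
#'   the last stage's count).
#' @return data.frame of class `funnel_report`: stage, count, removed
#'   (vs previous stage; negative means the stage added variants), and
#'   `share` = count / final rendered to two decimals.
#' @export
funnel_report <- function(stage_counts, final_count = NULL) {
  if (is.null(final_count)) final_count <- stage_counts[length(stage_counts)]
  removed <- c(NA, -diff(stage_counts))
  out <- data.frame(stage = names(stage_counts),
                    count = as.integer(stage_counts),
                    removed = as.integer(removed),
                    share = pct(stage_counts, final_count),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("funnel_report", "data.frame")
  out
}
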