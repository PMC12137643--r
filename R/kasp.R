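#' Encode marker genotypes as KASP-style R/A calls
#'
#' Reference-allele coding: dosage 0 -> `R/R`, 1 -> `R/A`, 2 -> `A/A`,
#' missing -> `missing`.
#'
#' @param x a `snp_data` object.
#' @param markers variant indices, or a data.frame with `chrom`, `pos`.
#' @return character matrix, samples x markers.
#' @export
encode_calls <- function(x, markers) {
  if (is.data.frame(markers)) {
    key <- paste(x$variants$chrom, x$variants$pos)
    markers <- match(paste(markers$chrom, markers$pos), key)
  }
  if (anyNA(markers)) stop("marker(s) absent from the genotype matrix")
  D <- x$dosage[, markers, drop = FALSE]
  codes <- matrix("missing", nrow(D), ncol(D),
                  dimnames = list(rownames(D), paste0("M", seq_len(ncol(D)))))
  codes[D == 0] <- "R/R"
  codes[D == 1] <- "R/A"
  codes[D == 2] <- "A/A"
  codes
}

#' Early-flowering call from a marker-code set
#'
#' The panel rule: an accession is called `early` when at least
#' `quorum` of its markers carry the alternate allele (`R/A` or `A/A`).
#' Missing markers never count toward the quorum; an accession with all
#' markers missing is `non_early` (flagged via the `all_missing`
#' attribute).
#'
#' @param codes character matrix from [encode_calls()] (or a vector for
#'   one accession).
#' @param quorum markers required (default 2, of the 3-marker set).
#' @return factor `early` / `non_early` per accession.
#' @export
classify_early <- function(codes, quorum = 2) {
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1)
  n_alt <- rowSums(codes == "R/A" | codes == "A/A")
  out <- factor(ifelse(n_alt >= quorum, "early", "non_early"),
                levels = c("early", "non_early"))
  attr(out, "all_missing") <- rowSums(codes != "missing") == 0
  out
}

#' Evaluate the early-flowering classifier against flowering dates
#'
#' Observed early = flowering day-of-year at or before `cutoff_doy`
#' (March 31 of a non-leap year = day 90). Group accuracies divide the
#' correct calls by the group size net of missing records; prevalence is
#' observed-early over records with dates. Percent values are rendered
#' half-up to one decimal, matching the panel-report convention.
#'
#' @param predictions factor from [classify_early()] (names or order
#'   aligned with `flowering_doy`).
#' @param flowering_doy integer day-of-year vector, NA = missing record.
#' @param cutoff_doy last early day (default 90).
#' @return List of class `kasp_report`: `counts` (2x3 confusion),
#'   `accuracy_early`, `accuracy_non_early`, `accuracy_overall`,
#'   `prevalence` (all in percent, 1 decimal).
#' @export
evaluate_kasp <- function(predictions, flowering_doy, cutoff_doy = 90) {
  if (!length(predictions)) stop("empty panel")
  stopifnot(length(predictions) == length(flowering_doy))
  obs <- ifelse(is.na(flowering_doy), "missing",
                ifelse(flowering_doy <= cutoff_doy, "early", "late"))
  counts <- table(pred = factor(predictions,
                                levels = c("early", "non_early")),
                  obs = factor(obs, levels = c("early", "late", "missing")))
  acc <- function(correct, total_nonmiss) {
    if (total_nonmiss == 0) return(NA_real_)
    round_half_up(100 * correct / total_nonmiss, 1)
  }
  ce <- counts["early", "early"]
  ne <- sum(counts["early", c("early", "late")])
  cl <- counts["non_early", "late"]
  nl <- sum(counts["non_early", c("early", "late")])
  structure(list(
    counts = counts,
    accuracy_early = acc(ce, ne),
    accuracy_non_early = acc(cl, nl),
    accuracy_overall = acc(ce + cl, ne + nl),
    prevalence = acc(sum(counts[, "early"]), ne + nl)),
    class = "kasp_report")
}

#' @export
print.kasp_report <- function(x, ...) {
  print(x$counts)
  cat(sprintf("early-call accuracy     %.1f%%\n", x$accuracy_early))
  cat(sprintf("non-early-call accuracy %.1f%%\n", x$accuracy_non_early))
  cat(sprintf("overall accuracy        %.1f%%\n", x$accuracy_overall))
  cat(sprintf("early prevalence        %.1f%%\n", x$prevalence))
  invisible(x)
}

#' Rank candidate block SNPs for a marker panel
#'
#' Heuristic panel selection: each candidate is scored by the
#' classification accuracy of its single-marker rule (alternate allele
#' present -> early) on a training panel; ties broken by call rate, then
#' association p-value, then position.
#'
#' @param x `snp_data` of the training panel.
#' @param candidates variant indices of the block SNPs.
#' @param flowering_doy observed day-of-year vector for the panel.
#' @param gwas_p association p-values aligned with `candidates`.
#' @param k markers to return (default 3).
#' @param cutoff_doy early-flowering cutoff (default 90).
#' @return data.frame of the top `k` candidates with their scores.
#' @export
select_markers <- function(x, candidates, flowering_doy, gwas_p = NULL,
                           k = 3, cutoff_doy = 90) {
  if (k > length(candidates)) {
    warning("fewer candidates than k; returning all")
    k <- length(candidates)
  }
  if (is.null(gwas_p)) gwas_p <- rep(NA_real_, length(candidates))
  obs_early <- flowering_doy <= cutoff_doy
  score <- cr <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    d <- x$dosage[, candidates[i]]
    pred_early <- !is.na(d) & d >= 1
    ok <- !is.na(obs_early)
    score[i] <- mean(pred_early[ok] == obs_early[ok])
    cr[i] <- mean(!is.na(d))
  }
  ord <- order(-score, -cr, gwas_p, x$variants$pos[candidates])
  sel <- ord[seq_len(k)]
  data.frame(variant = candidates[sel],
             chrom = x$variants$chrom[candidates[sel]],
             pos = x$variants$pos[candidates[sel]],
             accuracy = score[sel], call_rate = cr[sel],
             p = gwas_p[sel], stringsAsFactors = FALSE)
}
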