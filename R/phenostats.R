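#' Spearman correlation matrix with a significance mask
#'
#' Pairwise-complete Spearman rank correlations between traits, with a
#' mask marking pairs whose p-value is at or above `alpha` (the "X" cells
#' of the trait-correlation figure convention).
#'
#' @param phenotypes phenotype data.frame (accession, trait, year,
#'   value).
#' @param traits trait names to include.
#' @param year optional year filter.
#' @param alpha mask level (default 0.05).
#' @return List: `rho` (matrix), `p` (matrix), `not_significant`
#'   (logical mask, TRUE where p >= alpha).
#' @export
spearman_matrix <- function(phenotypes, traits, year = NULL,
                            alpha = 0.05) {
  ph <- phenotypes[phenotypes$trait %in% traits, , drop = FALSE]
  if (!is.null(year)) ph <- ph[ph$year == year, , drop = FALSE]
  wide <- stats::reshape(ph[, c("accession", "trait", "value")],
                         idvar = "accession", timevar = "trait",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  traits <- intersect(traits, names(wide))
  k <- length(traits)
  rho <- p <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      a <- wide[[traits[i]]]; b <- wide[[traits[j]]]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3) next
      if (i == j) { rho[i, j] <- 1; p[i, j] <- 0; next }
      ct <- suppressWarnings(stats::cor.test(a[ok], b[ok],
                                             method = "spearman"))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(rho = rho, p = p, not_significant = p >= alpha)
}

#' Normality-gated comparison of a cluster against the rest
#'
#' Shapiro-Wilk at `alpha_norm` on each group decides the branch: both
#' normal gives a two-sided Student's t test, otherwise a Mann-Whitney U
#' test. Both groups need at least 3 phenotyped members.
#'
#' @param phenotypes phenotype data.frame.
#' @param trait trait name.
#' @param cluster_members accession IDs of the cluster.
#' @param year optional year filter.
#' @param rest optional explicit comparison set (default: all other
#'   phenotyped accessions).
#' @param alpha_norm normality-gate level (default 0.05).
#' @return List: `test` ("student_t" or "mann_whitney"), `p`,
#'   `mean_cluster`, `mean_rest`, `n_cluster`, `n_rest`.
#' @export
cluster_vs_rest <- function(phenotypes, trait, cluster_members,
                            year = NULL, rest = NULL,
                            alpha_norm = 0.05) {
  ph <- phenotypes[phenotypes$trait == trait & !is.na(phenotypes$value), ,
                   drop = FALSE]
  if (!is.null(year)) ph <- ph[ph$year == year, , drop = FALSE]
  a <- ph$value[ph$accession %in% cluster_members]
  b <- if (is.null(rest)) ph$value[!ph$accession %in% cluster_members]
       else ph$value[ph$accession %in% rest]
  if (length(a) < 3 || length(b) < 3) stop("need >= 3 phenotyped members per group")
  normal <- function(v) {
    if (length(unique(v)) < 3) return(FALSE)
    stats::shapiro.test(v)$p.value >= alpha_norm
  }
  if (normal(a) && normal(b)) {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    test <- "student_t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    test <- "mann_whitney"
  }
  list(test = test, p = ht$p.value, mean_cluster = mean(a),
       mean_rest = mean(b), n_cluster = length(a), n_rest = length(b))
}

#' Descriptive trait summaries: sugar ratios and acid ratio range
#'
#' Mean-based component ratios normalized to the last component (the
#' sucrose:glucose:fructose:sorbitol convention) over samples with all
#' components non-missing, plus the per-sample malate/citrate ratio
#' range.
#'
#' @param phenotypes phenotype data.frame.
#' @param sugar_traits component traits, last one the reference.
#' @param year optional year filter.
#' @return List: `ratio` (numeric, rounded half-up to 2 decimals),
#'   `ratio_string` ("22.37:3.63:2.76:1" style), `malate_citrate_range`,
#'   `per_trait` (n, mean, median, IQR).
#' @export
trait_summary <- function(phenotypes,
                          sugar_traits = c("sucrose", "glucose",
                                           "fructose", "sorbitol"),
                          year = NULL) {
  ph <- phenotypes
  if (!is.null(year)) ph <- ph[ph$year == year, , drop = FALSE]
  get <- function(tr) {
    v <- ph[ph$trait == tr, c("accession", "value")]
    stats::setNames(v$value, v$accession)
  }
  comp <- lapply(sugar_traits, get)
  common <- Reduce(intersect, lapply(comp, function(v)
    names(v)[!is.na(v)]))
  means <- vapply(comp, function(v) mean(v[common]), 0)
  ratio <- round_half_up(means / means[length(means)], 2)
  fmt <- sub("\\.?0+$", "", sprintf("%.2f", ratio))
  mal <- get("malate"); cit <- get("citrate")
  shared <- intersect(names(mal)[!is.na(mal)], names(cit)[!is.na(cit)])
  shared <- shared[cit[shared] != 0]
  mc_range <- if (length(shared)) {
    round_half_up(range(mal[shared] / cit[shared]), 2)
  } else c(NA_real_, NA_real_)
  per_trait <- do.call(rbind, lapply(unique(ph$trait), function(tr) {
    v <- ph$value[ph$trait == tr]
    v <- v[!is.na(v)]
    data.frame(trait = tr, n = length(v), mean = mean(v),
               median = stats::median(v), IQR = stats::IQR(v),
               stringsAsFactors = FALSE)
  }))
  list(ratio = stats::setNames(ratio, sugar_traits),
       ratio_string = paste(fmt, collapse = ":"),
       malate_citrate_range = mc_range,
       per_trait = per_trait)
}

#' Flowering-date distribution and peak-day share
#'
#' @param phenotypes phenotype data.frame containing `flowering_date`
#'   rows (day-of-year integers).
#' @param year optional year filter.
#' @return List: `histogram` (day, n), `peak_day`, `peak_share_pct`
#'   (half-up, 2 decimals), `span_days`.
#' @export
flowering_distribution <- function(phenotypes, year = NULL) {
  ph <- phenotypes[phenotypes$trait == "flowering_date" &
                   !is.na(phenotypes$value), , drop = FALSE]
  if (!is.null(year)) ph <- ph[ph$year == year, , drop = FALSE]
  if (!nrow(ph)) stop("no flowering dates")
  tab <- table(ph$value)
  days <- as.integer(names(tab))
  hist <- data.frame(day = days, n = as.integer(tab))
  peak <- days[which.max(tab)]
  list(histogram = hist, peak_day = peak,
       peak_share_pct = round_half_up(100 * max(tab) / sum(tab), 2),
       span_days = diff(range(days)))
}
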