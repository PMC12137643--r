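#' Composite LD between two variants
#'
#' Squared Pearson correlation of dosage vectors over jointly non-missing
#' samples. Returns `NA` with fewer than 3 joint samples or if either
#' variant is constant among them.
#'
#' @param x a `snp_data` object.
#' @param i,j variant indices.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(x, i, j) {
  a <- x$dosage[, i]; b <- x$dosage[, j]
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
  stats::cor(a[ok], b[ok])^2
}

#' Greedy contiguous LD-block finder
#'
#' Grows a block along the map while the minimum r-squared between the
#' candidate SNP and every SNP already in the block stays at or above
#' `cut`; blocks of fewer than 2 SNPs are not emitted. A deliberately
#' simple, deterministic substitute for clique-partition block finders:
#' downstream analyses need only the block intervals.
#'
#' @param x a `snp_data` object (variants sorted by position).
#' @param region optional list/vector `(chrom, start, end)` restricting
#'   the scan.
#' @param cut minimum pairwise r-squared (default 0.6).
#' @return data.frame of class `ld_blocks`: chrom, start, end (bp),
#'   first, last (variant indices in `x`), n_snps.
#' @export
find_blocks <- function(x, region = NULL, cut = 0.6) {
  v <- x$variants
  idx_all <- seq_len(nrow(v))
  if (!is.null(region)) {
    region <- as.list(region)
    idx_all <- which(v$chrom == region[[1]] &
                     v$pos >= as.numeric(region[[2]]) &
                     v$pos <= as.numeric(region[[3]]))
  }
  out <- list()
  for (ch in unique(v$chrom[idx_all])) {
    idx <- idx_all[v$chrom[idx_all] == ch]
    i <- 1L
    while (i < length(idx)) {
      members <- idx[i]
      j <- i + 1L
      while (j <= length(idx)) {
        r2 <- vapply(members, function(mm) ld_r2(x, mm, idx[j]), 0)
        if (any(is.na(r2)) || min(r2) < cut) break
        members <- c(members, idx[j])
        j <- j + 1L
      }
      if (length(members) >= 2) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = v$pos[members[1]],
          end = v$pos[members[length(members)]],
          first = members[1], last = members[length(members)],
          n_snps = length(members), stringsAsFactors = FALSE)
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               first = integer(), last = integer(), n_snps = integer())
  rownames(res) <- NULL
  class(res) <- c("ld_blocks", "data.frame")
  res
}

#' Build haplotypes over an LD block from phased data
#'
#' Distinct allele strings over the block's variants, with carrier lists.
#' Haplotype copies containing a missing allele are excluded (counted).
#' Strings carried by fewer than `min_count` accessions are removed; the
#' rest are ordered by descending carrier count (Hap1, Hap2, ...).
#'
#' @param x phased `snp_data`.
#' @param block variant indices (or one row of [find_blocks()] output).
#' @param min_count minimum carrier count (default 2).
#' @return List of class `haplotype_set`: `haplotypes` (data.frame name,
#'   string, n_carriers, n_copies), `carriers` (list of accession
#'   vectors), `copy_assign` (2 rows per sample: haplotype name or NA),
#'   `n_excluded_copies`.
#' @export
build_haplotypes <- function(x, block, min_count = 2) {
  if (is.null(x$phased)) stop("phased haplotypes required")
  if (is.data.frame(block)) block <- seq(block$first[1], block$last[1])
  H <- x$phased[, block, drop = FALSE]
  n <- n_samples(x)
  ids <- rownames(x$dosage)
  strings <- apply(H, 1, function(r) {
    if (anyNA(r)) NA_character_ else paste(r, collapse = "")
  })
  n_excluded <- sum(is.na(strings))
  sample_of_row <- rep(seq_len(n), each = 2)
  tab_copies <- table(strings)
  carrier_list <- lapply(names(tab_copies), function(s) {
    unique(ids[sample_of_row[which(strings == s)]])
  })
  n_carriers <- lengths(carrier_list)
  keep <- n_carriers >= min_count
  o <- order(-n_carriers[keep], names(tab_copies)[keep])
  kept_strings <- names(tab_copies)[keep][o]
  hap_names <- paste0("Hap", seq_along(kept_strings))
  assign <- stats::setNames(rep(NA_character_, 2L * n), names(strings))
  for (h in seq_along(kept_strings)) {
    assign[which(strings == kept_strings[h])] <- hap_names[h]
  }
  list(
    haplotypes = data.frame(
      name = hap_names, string = kept_strings,
      n_carriers = n_carriers[keep][o],
      n_copies = as.integer(tab_copies[keep][o]),
      stringsAsFactors = FALSE),
    carriers = stats::setNames(carrier_list[keep][o], hap_names),
    copy_assign = matrix(assign, nrow = 2L * n, ncol = 1,
                         dimnames = list(names(strings), NULL)),
    samples = ids,
    n_excluded_copies = n_excluded) |>
    structure(class = "haplotype_set")
}

## Homozygous-carrier assignment: accession -> haplotype name, only when
## both copies carry the same retained string (ambiguous carriers NA).
hap_group_of <- function(hs) {
  n <- length(hs$samples)
  a <- hs$copy_assign[seq(1, 2 * n, 2), 1]
  b <- hs$copy_assign[seq(2, 2 * n, 2), 1]
  out <- ifelse(!is.na(a) & !is.na(b) & a == b, a, NA_character_)
  stats::setNames(out, hs$samples)
}

#' Compare a trait across haplotype groups (ANOVA + Fisher's LSD)
#'
#' Accessions are assigned to a haplotype group only when both copies
#' carry the same retained string. A one-way ANOVA is followed by
#' Fisher's least-significant-difference pairwise t tests (pooled MSE,
#' residual df, unadjusted p at `alpha`), with compact letter grouping.
#'
#' @param hs a `haplotype_set`.
#' @param phenotypes phenotype data.frame (accession, trait, year,
#'   value).
#' @param trait trait name to test.
#' @param year optional year filter.
#' @param alpha significance level for the letters (default 0.05).
#' @return List: `groups` (name, n, mean, letter), `anova_p`, `pairs`
#'   (pairwise LSD table).
#' @export
haplotype_phenotype_test <- function(hs, phenotypes, trait, year = NULL,
                                     alpha = 0.05) {
  ph <- phenotypes[phenotypes$trait == trait, , drop = FALSE]
  if (!is.null(year)) ph <- ph[ph$year == year, , drop = FALSE]
  grp <- hap_group_of(hs)
  ph$group <- grp[ph$accession]
  ph <- ph[!is.na(ph$group) & !is.na(ph$value), , drop = FALSE]
  counts <- table(ph$group)
  empty <- setdiff(names(hs$carriers), names(counts[counts >= 2]))
  if (length(empty)) {
    warning("group(s) dropped (fewer than 2 phenotyped carriers): ",
            paste(empty, collapse = ", "))
  }
  ph <- ph[ph$group %in% names(counts[counts >= 2]), , drop = FALSE]
  if (length(unique(ph$group)) < 2) stop("need >= 2 testable groups")
  ph$group <- factor(ph$group)
  fit <- stats::aov(value ~ group, data = ph)
  an <- summary(fit)[[1]]
  mse <- an["Residuals", "Mean Sq"]
  dfr <- an["Residuals", "Df"]
  means <- tapply(ph$value, ph$group, mean)
  ns <- tapply(ph$value, ph$group, length)
  gn <- names(means)
  pairs <- list()
  for (i in seq_along(gn)[-length(gn)]) {
    for (j in (i + 1):length(gn)) {
      se <- sqrt(mse * (1 / ns[i] + 1 / ns[j]))
      tval <- (means[i] - means[j]) / se
      pairs[[length(pairs) + 1L]] <- data.frame(
        a = gn[i], b = gn[j], diff = unname(means[i] - means[j]),
        t = unname(tval), p = unname(2 * stats::pt(-abs(tval), dfr)),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pairs)
  letters_vec <- lsd_letters(means, pairs, alpha)
  list(groups = data.frame(name = gn, n = as.integer(ns),
                           mean = unname(means),
                           letter = letters_vec[gn],
                           stringsAsFactors = FALSE),
       anova_p = an["group", "Pr(>F)"],
       pairs = pairs, mse = mse, df = dfr)
}

## Compact letter display: insert-and-absorb over means sorted
## descending; two groups share a letter iff not significantly different.
lsd_letters <- function(means, pairs, alpha) {
  gn <- names(sort(means, decreasing = TRUE))
  sig <- function(a, b) {
    r <- pairs[(pairs$a == a & pairs$b == b) |
               (pairs$a == b & pairs$b == a), ]
    nrow(r) > 0 && r$p[1] < alpha
  }
  groups <- list()  # each element: member names sharing a letter
  for (g in gn) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (!any(vapply(groups[[k]], function(o) sig(g, o), TRUE))) {
        groups[[k]] <- c(groups[[k]], g)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- g
  }
  out <- stats::setNames(rep("", length(gn)), gn)
  for (k in seq_along(groups)) {
    for (g in groups[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  out
}

#' Minimum-spanning haplotype network on Hamming distance
#'
#' Union of all minimum spanning trees (every tied minimal edge is
#' retained), built by Kruskal passes over equal-weight edge groups.
#' A documented stand-in for median-joining networks: no median vectors
#' are introduced.
#'
#' @param hs a `haplotype_set` (>= 2 haplotypes).
#' @return data.frame (from, to, weight = differing sites) plus
#'   attribute `divergence`: percent of sites differing from Hap1.
#' @export
haplotype_network <- function(hs) {
  h <- hs$haplotypes
  if (nrow(h) < 2) stop("need >= 2 haplotypes")
  n <- nrow(h)
  split_chars <- strsplit(h$string, "")
  dist_ij <- function(i, j) sum(split_chars[[i]] != split_chars[[j]])
  edges <- do.call(rbind, lapply(seq_len(n - 1), function(i) {
    do.call(rbind, lapply((i + 1):n, function(j) {
      data.frame(from = h$name[i], to = h$name[j],
                 weight = dist_ij(i, j), stringsAsFactors = FALSE)
    }))
  }))
  edges <- edges[order(edges$weight), , drop = FALSE]
  parent <- stats::setNames(seq_len(n), h$name)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  keep <- logical(nrow(edges))
  for (w in unique(edges$weight)) {
    grp <- which(edges$weight == w)
    # mark all edges joining distinct components at this weight...
    joins <- vapply(grp, function(e) {
      find(match(edges$from[e], h$name)) !=
        find(match(edges$to[e], h$name))
    }, TRUE)
    keep[grp[joins]] <- TRUE
    # ...then merge
    for (e in grp[joins]) {
      ri <- find(match(edges$from[e], h$name))
      rj <- find(match(edges$to[e], h$name))
      if (ri != rj) parent[ri] <- rj
    }
  }
  net <- edges[keep, , drop = FALSE]
  rownames(net) <- NULL
  L <- nchar(h$string[1])
  attr(net, "divergence") <- stats::setNames(
    vapply(seq_len(n), function(i) 100 * dist_ij(1, i) / L, 0), h$name)
  net
}

#' Haplotype frequency by kinship cluster
#'
#' Per-cluster share of accessions carrying each retained haplotype: an
#' accession distributes weight 1 equally across its retained copies, so
#' a heterozygous carrier of two different haplotypes contributes 0.5 to
#' each; accessions with no retained copy are excluded. Shares per
#' cluster sum to 1.
#'
#' @param hs a `haplotype_set`.
#' @param clusters named list of member-ID vectors (e.g. from
#'   [kinship_network()] clusters: `setNames(lapply(cl, [[,"members"),
#'   ids)`).
#' @return matrix clusters x haplotypes of shares.
#' @export
cluster_haplotype_freq <- function(hs, clusters) {
  hap_names <- hs$haplotypes$name
  n <- length(hs$samples)
  a <- hs$copy_assign[seq(1, 2 * n, 2), 1]
  b <- hs$copy_assign[seq(2, 2 * n, 2), 1]
  names(a) <- names(b) <- hs$samples
  out <- matrix(0, length(clusters), length(hap_names),
                dimnames = list(names(clusters), hap_names))
  for (k in seq_along(clusters)) {
    members <- intersect(clusters[[k]], hs$samples)
    for (s in members) {
      copies <- c(a[s], b[s])
      copies <- copies[!is.na(copies)]
      if (!length(copies)) next
      for (cp in copies) out[k, cp] <- out[k, cp] + 1 / length(copies)
    }
    tot <- sum(out[k, ])
    if (tot > 0) out[k, ] <- out[k, ] / tot
  }
  out
}
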