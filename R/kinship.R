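#' Genomic relationship matrix from SNP dosages
#'
#' Centered GRM on the relatedness scale: dosages are mean-imputed per
#' variant, column-centered at `2p`, and `K = Z Z' / sum(2 p_k (1 - p_k))`
#' so that a non-inbred self is ~1, parent-offspring ~0.5 and self with
#' inbreeding ~`1 + F`. Monomorphic (and all-missing) variants are
#' dropped. `method = "standardized"` instead scales each variant to unit
#' variance and divides by the marker count.
#'
#' @param x a `snp_data` object (or a plain samples-x-variants dosage
#'   matrix).
#' @param method `"centered"` (default) or `"standardized"`.
#' @return A symmetric kinship matrix with sample IDs as dimnames and
#'   attribute `provenance = "snp"`.
#' @export
grm <- function(x, method = c("centered", "standardized")) {
  method <- match.arg(method)
  D <- if (inherits(x, "snp_data")) x$dosage else x
  if (nrow(D) < 2) stop("need >= 2 samples")
  p <- colMeans(D, na.rm = TRUE) / 2
  all_missing <- is.nan(p)
  mono <- !all_missing & (p == 0 | p == 1)
  if (any(all_missing)) warning(sum(all_missing), " all-missing variant(s) dropped")
  keep <- !all_missing & !mono
  D <- D[, keep, drop = FALSE]
  p <- p[keep]
  if (!ncol(D)) stop("no polymorphic variants left")
  Z <- sweep(D, 2, 2 * p)
  Z[is.na(Z)] <- 0  # mean imputation after centering
  K <- if (method == "centered") {
    tcrossprod(Z) / sum(2 * p * (1 - p))
  } else {
    Zs <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
    tcrossprod(Zs) / ncol(Zs)
  }
  dimnames(K) <- list(rownames(D), rownames(D))
  attr(K, "provenance") <- "snp"
  K
}

#' Pedigree-based relatedness with a sport (clonal mutant) convention
#'
#' Recursive tabular kinship with inbreeding, computed in topological
#' order: `phi(i,i) = (1 + phi(s,d)) / 2`, `phi(i,j) = (phi(s,j) +
#' phi(d,j)) / 2`. A sport is a clone: its kinship row duplicates its
#' source cultivar's. Output is on the relatedness scale (`2 phi`, self =
#' `1 + F`); sport-source pairs are then overridden to `sport_value`,
#' mirroring the array-panel convention for bud mutations.
#'
#' @param pedigree a `pedigree_table`.
#' @param sport_value relatedness assigned to sport/source pairs
#'   (default 0.97).
#' @return A symmetric relatedness matrix over all pedigree individuals
#'   (external founder parents included), attribute `provenance =
#'   "pedigree"`.
#' @export
pedigree_kinship <- function(pedigree, sport_value = 0.97) {
  ids <- pedigree_topo_order(pedigree)
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  sire <- dam <- rep(NA_integer_, n)
  sport_of <- rep(NA_integer_, n)
  for (r in seq_len(nrow(pedigree))) {
    i <- idx[[pedigree$individual[r]]]
    if (pedigree$relation_type[r] == "sport") {
      p <- if (is.na(pedigree$sire[r])) pedigree$dam[r] else pedigree$sire[r]
      sport_of[i] <- idx[[p]]
    } else {
      if (!is.na(pedigree$sire[r])) sire[i] <- idx[[pedigree$sire[r]]]
      if (!is.na(pedigree$dam[r]))  dam[i]  <- idx[[pedigree$dam[r]]]
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {  # ids are topologically ordered
    if (!is.na(sport_of[i])) {
      p <- sport_of[i]
      phi[i, ] <- phi[p, ]; phi[, i] <- phi[, p]
      phi[i, i] <- phi[p, p]
      next
    }
    s <- sire[i]; d <- dam[i]
    before <- seq_len(i - 1L)
    if (length(before)) {
      v <- 0.5 * ((if (!is.na(s)) phi[s, before] else 0) +
                  (if (!is.na(d)) phi[d, before] else 0))
      phi[i, before] <- v
      phi[before, i] <- v
    }
    phi[i, i] <- 0.5 * (1 + if (!is.na(s) && !is.na(d)) phi[s, d] else 0)
  }
  K <- 2 * phi
  for (i in which(!is.na(sport_of))) {
    K[i, sport_of[i]] <- K[sport_of[i], i] <- sport_value
  }
  attr(K, "provenance") <- "pedigree"
  K
}

#' Monte-Carlo gene-dropping estimate of pedigree kinship
#'
#' Independent check of [pedigree_kinship()]: founders get unique allele
#' labels, alleles are dropped through the pedigree `n_rep` times, and
#' `phi(i,j)` is estimated as the probability a random allele from each is
#' identical by descent. Sports copy the parent's pair (clone). Returned
#' on the relatedness (`2 phi`) scale, without the sport override.
#'
#' @param pedigree a `pedigree_table`.
#' @param n_rep number of gene drops.
#' @param seed RNG seed.
#' @return A relatedness matrix over the pedigree individuals.
#' @export
kinship_mc <- function(pedigree, n_rep = 10000, seed = 1) {
  set.seed(seed)
  ids <- pedigree_topo_order(pedigree)
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  type <- stats::setNames(rep("founder", n), ids)
  s_of <- d_of <- stats::setNames(rep(NA_integer_, n), ids)
  for (r in seq_len(nrow(pedigree))) {
    id <- pedigree$individual[r]
    if (is.na(pedigree$sire[r]) && is.na(pedigree$dam[r])) next
    type[id] <- pedigree$relation_type[r]
    s_of[id] <- if (!is.na(pedigree$sire[r])) idx[[pedigree$sire[r]]] else NA
    d_of[id] <- if (!is.na(pedigree$dam[r])) idx[[pedigree$dam[r]]] else NA
  }
  acc <- matrix(0, n, n, dimnames = list(ids, ids))
  a1 <- a2 <- integer(n)
  for (rep_i in seq_len(n_rep)) {
    lab <- 0L
    for (i in seq_len(n)) {
      if (type[i] == "founder") {
        a1[i] <- lab + 1L; a2[i] <- lab + 2L; lab <- lab + 2L
      } else if (type[i] == "sport") {
        p <- if (is.na(s_of[i])) d_of[i] else s_of[i]
        a1[i] <- a1[p]; a2[i] <- a2[p]
      } else {
        s <- s_of[i]; d <- d_of[i]
        a1[i] <- if (stats::runif(1) < 0.5) a1[s] else a2[s]
        a2[i] <- if (stats::runif(1) < 0.5) a1[d] else a2[d]
      }
    }
    ibd <- 0.25 * (outer(a1, a1, "==") + outer(a1, a2, "==") +
                   outer(a2, a1, "==") + outer(a2, a2, "=="))
    acc <- acc + ibd
  }
  2 * acc / n_rep
}

#' Pearson correlation of SNP and pedigree kinship over known pairs
#'
#' @param K_snp,K_ped kinship matrices sharing sample IDs.
#' @param pairs data.frame with columns `a`, `b` listing the pedigree
#'   records to correlate over.
#' @return `htest`-like list with `r`, `p`, `n`.
#' @export
kinship_correlation <- function(K_snp, K_ped, pairs) {
  if (nrow(pairs) < 3) stop("need >= 3 pairs")
  get <- function(K) {
    ia <- match(pairs$a, rownames(K)); ib <- match(pairs$b, rownames(K))
    if (anyNA(ia) || anyNA(ib)) stop("pair member missing from a matrix")
    K[cbind(ia, ib)]
  }
  x <- get(K_snp); y <- get(K_ped)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: constant kinship values, correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pairs))
}

#' Method-of-moments inbreeding coefficient per sample
#'
#' `F = (O_hom - E_hom) / (m - E_hom)` with `E_hom = sum(1 - 2 p_k (1 -
#' p_k))` over the sites used; allele frequencies come from the panel,
#' monomorphic sites are excluded, and missing calls are excluded per
#' sample (both from `O_hom` and from the site sum).
#'
#' @param x a `snp_data` object.
#' @return Named numeric vector of F values (`NA` for samples with no
#'   usable calls).
#' @export
inbreeding_f <- function(x) {
  p <- alt_freq(x)
  poly <- !is.na(p) & p > 0 & p < 1
  D <- x$dosage[, poly, drop = FALSE]
  p <- p[poly]
  e_site <- 1 - 2 * p * (1 - p)
  apply_f <- function(row) {
    ok <- !is.na(row)
    m <- sum(ok)
    if (m == 0) return(NA_real_)
    o_hom <- sum(row[ok] != 1)
    e_hom <- sum(e_site[ok])
    (o_hom - e_hom) / (m - e_hom)
  }
  stats::setNames(apply(D, 1, apply_f), rownames(x$dosage))
}

#' Threshold network clustering of a kinship matrix
#'
#' Builds a graph with an edge wherever relatedness strictly exceeds
#' `threshold`; connected components with at least `min_cluster` members
#' become clusters (Clr1 = largest), smaller components are reported as
#' isolated pairs/small groups. Per-member degree and cluster mean
#' connectivity are emitted.
#'
#' @param K symmetric kinship matrix with sample IDs.
#' @param threshold edge rule is `K > threshold` (strict; default 0.45).
#' @param min_cluster minimum component size for a named cluster.
#' @return List with `clusters` (list of `cluster_id`, `members`,
#'   `degree`, `mean_connectivity`), `membership` (data.frame), `small`
#'   (members of sub-threshold-size components) and `unconnected`.
#' @export
kinship_network <- function(K, threshold = 0.45, min_cluster = 3) {
  A <- (K > threshold)
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  ids <- rownames(K)
  comp_sizes <- comp$csize
  big <- which(comp_sizes >= min_cluster)
  # order: size desc, then smallest member id for determinism
  first_member <- vapply(big, function(ci) min(ids[comp$membership == ci]), "")
  ord <- big[order(-comp_sizes[big], first_member)]
  clusters <- lapply(seq_along(ord), function(k) {
    members <- ids[comp$membership == ord[k]]
    list(cluster_id = paste0("Clr", k), members = members,
         degree = deg[members],
         mean_connectivity = mean(deg[members]))
  })
  small_comp <- which(comp_sizes >= 2 & comp_sizes < min_cluster)
  small <- ids[comp$membership %in% small_comp]
  unconnected <- ids[deg == 0]
  membership <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster = cl$cluster_id, member = cl$members,
               degree = unname(cl$degree), stringsAsFactors = FALSE)
  }))
  list(clusters = clusters,
       membership = membership %||% data.frame(cluster = character(),
                                               member = character(),
                                               degree = integer()),
       small = small, unconnected = unconnected)
}

#' Per-cluster share of the clustered accessions
#'
#' @param clusters the `clusters` element of [kinship_network()] output.
#' @return data.frame with cluster id, size, and the share of the
#'   clustered total rendered to two decimals ("29.35%").
#' @export
cluster_share <- function(clusters) {
  if (!length(clusters)) {
    return(data.frame(cluster = character(), size = integer(),
                      share = character()))
  }
  sizes <- vapply(clusters, function(cl) length(cl$members), 0L)
  total <- sum(sizes)
  data.frame(cluster = vapply(clusters, `[[`, "", "cluster_id"),
             size = sizes, share = pct(sizes, total),
             stringsAsFactors = FALSE)
}
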