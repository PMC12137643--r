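#' Simulation configuration for the orchard-population generator
#'
#' Defines the synthetic study population: founder diversity, genome and
#' genetic map, pedigree descent, planted QTLs, and genotyping artifacts.
#' Defaults emulate a multi-family inbred orchard panel on an 8-chromosome
#' genome: one major flowering locus and two fruit-acid loci, clonal
#' "sport" mutants carrying a handful of private mutations, and
#' short-read-style depth/quality artifacts.
#'
#' @param n_founders number of founder accessions (>= 2).
#' @param n_variants total SNP count across the genome.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param maf_min,maf_max founder ALT-frequency distribution is uniform on
#'   `[maf_min, maf_max]`.
#' @param inbred_founder_frac fraction of founders derived by one
#'   generation of selfing (segmental inbreeding, F = 0.5 in
#'   expectation). The default 0.7 anchors the founder-pool mean F at
#'   ~0.35, the inbreeding level of landrace germplasm in
#'   self-compatible orchard crops, and puts expected full-sib
#'   relatedness near the observed ~0.63 rather than the outbred 0.5;
#'   set to 0 for a fully outbred Hardy-Weinberg panel.
#' @param cm_per_mb constant genetic-map scaling (Haldane model).
#' @param n_mut number of random genotype changes a sport mutant carries
#'   relative to its source cultivar.
#' @param qtl data.frame with columns `chrom`, `pos`, `trait`, `pve`
#'   (target phenotypic variance explained per locus), and optionally
#'   `freq` (founder ALT frequency forced at the locus; NA = as drawn)
#'   and `sign` (+1: ALT raises the trait, -1: lowers it). The default
#'   flowering locus carries a low-frequency ALT allele that advances
#'   flowering, the structure seen for early-flowering haplotypes.
#' @param trait_scale data.frame with columns `trait`, `mean`, `sd` giving
#'   the measurement scale each standardized phenotype is mapped onto.
#' @param missing_rate,mean_depth,error_rate,gq_per_read genotyping
#'   artifact model used by [degrade_calls()].
#' @param hot_frac fraction of variants with pathological artifacts
#'   (missing rate drawn uniform on `[0.4, 0.8]`, depth cut to a
#'   quarter), emulating the bad tail of sequencing-derived candidate
#'   SNPs that the QC cascade exists to remove.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 24,
                       n_variants = 8000,
                       chrom_lengths = stats::setNames(rep(28e6, 8),
                                                       paste0("Chr", 1:8)),
                       maf_min = 0.05, maf_max = 0.5,
                       inbred_founder_frac = 0.7,
                       cm_per_mb = 4,
                       n_mut = 5,
                       qtl = data.frame(
                         chrom = c("Chr1", "Chr5", "Chr8"),
                         pos = c(20e6, 10e6, 17e6),
                         trait = c("flowering_date", "TA", "citrate"),
                         pve = c(0.35, 0.29, 0.07),
                         freq = c(0.10, NA, NA),
                         sign = c(-1, 1, 1),
                         stringsAsFactors = FALSE),
                       trait_scale = data.frame(
                         trait = c("flowering_date", "TA", "citrate",
                                   "SSC", "pH", "sucrose", "glucose",
                                   "fructose", "sorbitol", "malate",
                                   "quinate", "shikimate"),
                         mean = c(94, 5.2, 1.6, 12.5, 3.9, 58.5, 9.5,
                                  7.2, 2.6, 3.1, 0.6, 0.05),
                         sd = c(3.2, 1.4, 0.5, 1.8, 0.35, 12, 2.4, 1.8,
                                0.9, 1.1, 0.25, 0.02),
                         stringsAsFactors = FALSE),
                       missing_rate = 0.02, mean_depth = 10,
                       error_rate = 0.01, gq_per_read = 10,
                       hot_frac = 0.1) {
  stopifnot(n_founders >= 2, n_variants >= 0, all(chrom_lengths > 0),
            maf_min > 0, maf_max <= 0.5, maf_min <= maf_max,
            inbred_founder_frac >= 0, inbred_founder_frac <= 1)
  pve_sum <- tapply(qtl$pve, qtl$trait, sum)
  if (any(pve_sum >= 1)) stop("per-trait QTL PVE must sum to < 1")
  structure(as.list(environment()), class = "sim_config")
}

## One base seed, one named stream per stochastic operation.
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 65011L)
}

## Per-chromosome marker indices, physical spans and genetic lengths.
chrom_map <- function(v, config) {
  chrom_idx <- split(seq_len(nrow(v)), v$chrom)
  spans <- vapply(names(chrom_idx), function(ch) {
    s <- config$chrom_lengths[ch]
    if (is.na(s)) s <- max(v$pos[chrom_idx[[ch]]])
    unname(s)
  }, 0)
  list(idx = chrom_idx, span = spans,
       morgans = spans * config$cm_per_mb / 1e6 / 100)
}

## One meiosis under the Haldane model: Poisson crossover count per
## chromosome, uniform positions; recombines haplotypes (and their origin
## labels) into a gamete.
make_gamete <- function(h1, h2, o1, o2, v, map) {
  m <- length(h1)
  g <- integer(m); go <- integer(m)
  for (ci in seq_along(map$idx)) {
    idx <- map$idx[[ci]]
    n_co <- stats::rpois(1, map$morgans[ci])
    cuts <- sort(stats::runif(n_co, 0, map$span[ci]))
    parity <- (findInterval(v$pos[idx], cuts) + sample.int(2L, 1L)) %% 2L
    g[idx]  <- ifelse(parity == 0L, h1[idx], h2[idx])
    go[idx] <- ifelse(parity == 0L, o1[idx], o2[idx])
  }
  list(g = g, o = go)
}

#' Simulate founder accessions with phased haplotypes
#'
#' Founder ALT frequencies are drawn from the configured uniform
#' distribution; the two haplotypes of each founder are paired at random
#' (Hardy-Weinberg). Variant positions are uniform per chromosome, with
#' variant counts proportional to chromosome length.
#'
#' @param config a [sim_config()].
#' @param seed base seed for this run.
#' @return A phased `snp_data` object; founder samples are named `F1..Fn`.
#'   The founder ALT frequencies are attached as attribute `founder_freq`.
#' @export
simulate_founders <- function(config, seed = 1) {
  set.seed(stream_seed(seed, "founders"))
  m <- config$n_variants
  n <- config$n_founders
  cl <- config$chrom_lengths
  m_per <- if (m == 0) integer(length(cl)) else
    as.integer(round(m * cl / sum(cl)))
  # keep the total exactly m
  while (sum(m_per) != m) {
    i <- which.max(cl)
    m_per[i] <- m_per[i] + sign(m - sum(m_per))
  }
  variants <- do.call(rbind, lapply(seq_along(cl), function(i) {
    if (m_per[i] == 0) return(NULL)
    pos <- sort(sample.int(cl[i], m_per[i]))
    data.frame(chrom = names(cl)[i], pos = pos, stringsAsFactors = FALSE)
  }))
  if (is.null(variants)) variants <- data.frame(chrom = character(),
                                                pos = integer())
  bases <- c("A", "C", "G", "T")
  variants$ref <- sample(bases, m, replace = TRUE)
  variants$alt <- vapply(variants$ref,
                         function(r) sample(setdiff(bases, r), 1), "")
  variants$qual <- rep(500, m)
  variants$stage_flags <- rep("", m)
  freq <- stats::runif(m, config$maf_min, config$maf_max)
  if (!is.null(config$qtl$freq)) {
    # force the configured founder frequency at planted QTL sites
    for (i in which(!is.na(config$qtl$freq))) {
      on_chr <- which(variants$chrom == config$qtl$chrom[i])
      if (length(on_chr)) {
        j <- on_chr[which.min(abs(variants$pos[on_chr] -
                                  config$qtl$pos[i]))]
        freq[j] <- config$qtl$freq[i]
      }
    }
  }
  phased <- matrix(stats::rbinom(2L * n * m, 1L, rep(freq, each = 2L * n)),
                   nrow = 2L * n, ncol = m)
  n_inbred <- round(config$inbred_founder_frac * n)
  if (n_inbred > 0 && m > 0) {
    # inbred founders: one generation of selfing on the drawn diplotype,
    # realized segmentally through recombination (F = 0.5 in expectation)
    map <- chrom_map(variants, config)
    for (i in sample.int(n, n_inbred)) {
      h1 <- phased[2 * i - 1, ]; h2 <- phased[2 * i, ]
      phased[2 * i - 1, ] <- make_gamete(h1, h2, h1, h2, variants, map)$g
      phased[2 * i, ]     <- make_gamete(h1, h2, h1, h2, variants, map)$g
    }
  }
  dosage <- phased[seq(1, 2 * n, 2), , drop = FALSE] +
            phased[seq(2, 2 * n, 2), , drop = FALSE]
  rownames(dosage) <- paste0("F", seq_len(n))
  rownames(phased) <- paste0(rep(rownames(dosage), each = 2), c("_h1", "_h2"))
  x <- snp_data(variants, dosage, phased = phased)
  attr(x, "founder_freq") <- freq
  x
}

#' Drop genes through a pedigree with recombination
#'
#' Each meiosis draws a Poisson number of crossovers per chromosome
#' (Haldane model, rate `cm_per_mb`), placed uniformly, and transmits the
#' resulting gamete. Sport offspring copy the source cultivar's diplotype
#' and then mutate `n_mut` random sites on one haplotype. Every founder
#' haplotype carries a unique origin label that descends with the DNA, so
#' the realized IBD structure is known exactly.
#'
#' @param founders phased `snp_data` from [simulate_founders()]; sample
#'   names must cover every pedigree root.
#' @param pedigree a `pedigree_table` (see [read_pedigree()]); rows with
#'   both parents missing are founders.
#' @param config the [sim_config()] (for map scaling and `n_mut`).
#' @param seed base seed.
#' @return A phased `snp_data` containing every pedigree individual, with
#'   attribute `origin`: an integer matrix (2 rows per sample) of founder
#'   haplotype labels — the truth set for IBD and kinship checks.
#' @export
gene_drop <- function(founders, pedigree, config, seed = 1) {
  set.seed(stream_seed(seed, "gene_drop"))
  v <- founders$variants
  m <- nrow(v)
  ids <- pedigree$individual
  is_founder <- is.na(pedigree$sire) & is.na(pedigree$dam)
  roots <- ids[is_founder]
  missing_founders <- setdiff(roots, rownames(founders$dosage))
  if (length(missing_founders)) {
    stop("founder genotypes missing for: ",
         paste(missing_founders, collapse = ", "))
  }
  unref <- setdiff(rownames(founders$dosage), roots)
  if (length(unref)) warning(length(unref), " founder(s) never referenced")

  map <- chrom_map(v, config)
  n_out <- length(ids)
  hap <- matrix(NA_integer_, nrow = 2L * n_out, ncol = m)
  org <- matrix(NA_integer_, nrow = 2L * n_out, ncol = m)
  rownames(hap) <- paste0(rep(ids, each = 2), c("_h1", "_h2"))
  row_of <- stats::setNames(seq_len(n_out), ids)

  founder_row <- stats::setNames(seq_len(nrow(founders$dosage)),
                                 rownames(founders$dosage))

  topo <- intersect(pedigree_topo_order(pedigree), ids)
  for (id in topo) {
    i <- row_of[[id]]
    r <- which(pedigree$individual == id)
    sire <- pedigree$sire[r]; dam <- pedigree$dam[r]
    if (is.na(sire) && is.na(dam)) {
      fr <- founder_row[[id]]
      hap[2 * i - 1, ] <- founders$phased[2 * fr - 1, ]
      hap[2 * i, ]     <- founders$phased[2 * fr, ]
      org[2 * i - 1, ] <- 2L * fr - 1L
      org[2 * i, ]     <- 2L * fr
    } else if (pedigree$relation_type[r] == "sport") {
      p <- row_of[[if (is.na(sire)) dam else sire]]
      hap[2 * i - 1, ] <- hap[2 * p - 1, ]
      hap[2 * i, ]     <- hap[2 * p, ]
      org[2 * i - 1, ] <- org[2 * p - 1, ]
      org[2 * i, ]     <- org[2 * p, ]
      if (config$n_mut > 0 && m > 0) {
        sites <- sample.int(m, min(config$n_mut, m))
        rowm <- 2 * i - sample.int(2L, 1L) + 1L  # one haplotype at random
        hap[rowm, sites] <- 1L - hap[rowm, sites]
      }
    } else {
      if (is.na(sire) || is.na(dam)) {
        stop("cross offspring ", id, " is missing a parent")
      }
      ps <- row_of[[sire]]; pd <- row_of[[dam]]
      gs <- make_gamete(hap[2 * ps - 1, ], hap[2 * ps, ],
                        org[2 * ps - 1, ], org[2 * ps, ], v, map)
      gd <- make_gamete(hap[2 * pd - 1, ], hap[2 * pd, ],
                        org[2 * pd - 1, ], org[2 * pd, ], v, map)
      hap[2 * i - 1, ] <- gs$g; org[2 * i - 1, ] <- gs$o
      hap[2 * i, ] <- gd$g;     org[2 * i, ] <- gd$o
    }
  }
  dosage <- hap[seq(1, 2 * n_out, 2), , drop = FALSE] +
            hap[seq(2, 2 * n_out, 2), , drop = FALSE]
  rownames(dosage) <- ids
  x <- snp_data(v, dosage, phased = hap)
  attr(x, "origin") <- org
  x
}

#' True IBD segments for one sample pair from gene-drop origin labels
#'
#' A pair is IBD over a marker run where some haplotype combination shares
#' the founder origin label. Runs shorter than `min_markers` or `min_bp`
#' are dropped; intervals from the four combinations are unioned.
#'
#' @param x gene-dropped `snp_data` with an `origin` attribute.
#' @param a,b sample names or indices.
#' @param min_markers,min_bp minimum run size filters.
#' @return An `ibd_segments` data.frame.
#' @export
truth_ibd <- function(x, a, b, min_markers = 2, min_bp = 0) {
  org <- attr(x, "origin")
  if (is.null(org)) stop("no origin labels: not a gene_drop result")
  if (is.character(a)) a <- match(a, rownames(x$dosage))
  if (is.character(b)) b <- match(b, rownames(x$dosage))
  segs <- list()
  v <- x$variants
  for (ha in c(2 * a - 1, 2 * a)) {
    for (hb in c(2 * b - 1, 2 * b)) {
      eq <- org[ha, ] == org[hb, ]
      segs[[length(segs) + 1]] <-
        runs_to_segments(eq, v, min_markers, min_bp, g = 0)
    }
  }
  seg <- do.call(rbind, segs)
  if (is.null(seg) || nrow(seg) == 0) {
    return(merge_pair_segments(data.frame(
      sample_a = character(), sample_b = character(), chrom = character(),
      start = integer(), end = integer(), score = numeric())))
  }
  nm <- sort(c(rownames(x$dosage)[a], rownames(x$dosage)[b]))
  seg$sample_a <- nm[1]; seg$sample_b <- nm[2]
  merge_pair_segments(seg)
}

#' Simulate phenotypes with planted QTLs
#'
#' Builds `y = sum(beta_k x_k) + g + e` per trait: each QTL effect is
#' scaled so its realized variance share matches the target PVE given the
#' observed dosage variance; `g` is an optional polygenic term built from
#' `n_background` random markers; `e` is Gaussian noise filling the
#' remaining variance. The standardized value is mapped onto the trait's
#' measurement scale (day-of-year for flowering, concentration units
#' otherwise).
#'
#' @param x a `snp_data` object.
#' @param config a [sim_config()]; its `qtl` rows are snapped to the
#'   nearest simulated variant.
#' @param seed base seed.
#' @param year year label recorded in the table.
#' @param h2_poly variance share of the polygenic background term.
#' @param n_background number of background markers for the polygenic term.
#' @return A phenotype data.frame (accession, trait, year, value) with
#'   attribute `truth`: per-QTL variant index, beta (standardized scale)
#'   and realized variance share.
#' @export
simulate_phenotypes <- function(x, config, seed = 1, year = 2016,
                                h2_poly = 0, n_background = 200) {
  set.seed(stream_seed(seed, "phenotypes"))
  v <- x$variants
  n <- n_samples(x)
  qtl <- config$qtl
  qtl$idx <- vapply(seq_len(nrow(qtl)), function(i) {
    on_chr <- which(v$chrom == qtl$chrom[i])
    if (!length(on_chr)) stop("QTL chromosome ", qtl$chrom[i],
                              " absent from variant set")
    on_chr[which.min(abs(v$pos[on_chr] - qtl$pos[i]))]
  }, 0L)
  out <- list(); truth <- list()
  for (tr in unique(qtl$trait)) {
    rows <- qtl[qtl$trait == tr, , drop = FALSE]
    y <- numeric(n); used <- NULL
    for (i in seq_len(nrow(rows))) {
      xk <- x$dosage[, rows$idx[i]]
      xk[is.na(xk)] <- mean(xk, na.rm = TRUE)
      vx <- stats::var(xk)
      if (vx == 0) stop("monomorphic QTL site at ", rows$chrom[i], ":",
                        rows$pos[i], " — target PVE unattainable")
      beta <- sqrt(rows$pve[i] / vx) *
        (if (!is.null(rows$sign)) rows$sign[i] else 1)
      y <- y + beta * xk
      used <- rbind(used, data.frame(trait = tr, idx = rows$idx[i],
                                     chrom = rows$chrom[i],
                                     pos = v$pos[rows$idx[i]],
                                     beta = beta, target_pve = rows$pve[i]))
    }
    if (h2_poly > 0 && n_variants(x) > nrow(rows)) {
      bg <- sample(setdiff(seq_len(n_variants(x)), rows$idx),
                   min(n_background, n_variants(x) - nrow(rows)))
      Zb <- x$dosage[, bg, drop = FALSE]
      Zb[is.na(Zb)] <- 0
      gpoly <- Zb %*% stats::rnorm(length(bg))
      gpoly <- drop(scale(gpoly)) * sqrt(h2_poly)
      y <- y + gpoly
    }
    resid_var <- 1 - sum(rows$pve) - h2_poly
    y <- y + stats::rnorm(n, 0, sqrt(max(resid_var, 0)))
    for (i in seq_len(nrow(rows))) {
      xk <- x$dosage[, rows$idx[i]]
      xk[is.na(xk)] <- mean(xk, na.rm = TRUE)
      used$realized_pve[i] <-
        used$beta[i]^2 * stats::var(xk) / stats::var(y)
    }
    truth[[tr]] <- used
    sc <- config$trait_scale[config$trait_scale$trait == tr, , drop = FALSE]
    if (nrow(sc) == 0) sc <- data.frame(mean = 0, sd = 1)
    val <- sc$mean[1] + sc$sd[1] * (y - mean(y))
    if (tr == "flowering_date") val <- as.integer(round(val))
    else val <- pmax(val, 0.1)  # measurement floor; values are positive
    out[[tr]] <- data.frame(accession = rownames(x$dosage), trait = tr,
                            year = year, value = val,
                            stringsAsFactors = FALSE)
  }
  # traits with no planted QTL are environment-only on their scale
  for (tr in setdiff(config$trait_scale$trait, unique(qtl$trait))) {
    sc <- config$trait_scale[config$trait_scale$trait == tr, ]
    val <- sc$mean + sc$sd * stats::rnorm(n)
    if (tr == "flowering_date") val <- as.integer(round(val))
    else val <- pmax(val, 0.1)
    out[[tr]] <- data.frame(accession = rownames(x$dosage), trait = tr,
                            year = year, value = val,
                            stringsAsFactors = FALSE)
  }
  ph <- do.call(rbind, out)
  rownames(ph) <- NULL
  attr(ph, "truth") <- do.call(rbind, truth)
  ph
}

#' Inject genotyping artifacts (missingness, depth, quality, call errors)
#'
#' Per-call depth is Poisson(`mean_depth`); calls with depth 0 are missing;
#' additional calls are masked at `missing_rate`; GQ is the monotone
#' function `min(99, gq_per_read * DP)`; a fraction `error_rate` of
#' surviving calls is flipped to a different dosage; variant-level allele
#' quality (QUAL) is `min(999, 3 * total depth at the variant)`.
#'
#' @param x a clean `snp_data` object (truth).
#' @param config a [sim_config()] supplying the artifact model.
#' @param seed base seed.
#' @param missing_rate,mean_depth,error_rate,hot_frac overrides of the
#'   config values; `missing_rate` may be a per-variant vector (in which
#'   case `hot_frac` is ignored).
#' @return A degraded `snp_data` (phase dropped) with attribute `truth`
#'   holding the original dosage matrix.
#' @export
degrade_calls <- function(x, config, seed = 1,
                          missing_rate = config$missing_rate,
                          mean_depth = config$mean_depth,
                          error_rate = config$error_rate,
                          hot_frac = config$hot_frac) {
  set.seed(stream_seed(seed, "degrade"))
  n <- n_samples(x); m <- n_variants(x)
  dosage <- x$dosage
  rate <- rep(missing_rate, length.out = m)
  depth <- rep(mean_depth, length.out = m)
  if (length(missing_rate) == 1 && hot_frac > 0 && m > 0) {
    hot <- sample.int(m, round(hot_frac * m))
    rate[hot] <- stats::runif(length(hot), 0.4, 0.8)
    depth[hot] <- mean_depth / 4
  }
  dp <- matrix(stats::rpois(n * m, rep(depth, each = n)), n, m)
  mask <- matrix(stats::runif(n * m) < rep(rate, each = n), n, m) | dp == 0
  if (error_rate > 0) {
    err <- matrix(stats::runif(n * m) < error_rate, n, m) & !mask
    if (any(err)) {
      dosage[err] <- (dosage[err] + sample(1:2, sum(err), replace = TRUE)) %% 3L
    }
  }
  dosage[mask] <- NA_integer_
  dp[mask] <- 0L
  gq <- config$gq_per_read * dp
  gq[gq > 99L] <- 99L
  v <- x$variants
  v$qual <- pmin(999, 3 * colSums(dp))
  out <- snp_data(v, dosage, dp = dp, gq = gq)
  attr(out, "truth") <- x$dosage
  out
}

#' Script a multi-family orchard pedigree
#'
#' Convenience generator for the descent structure the analyses assume:
#' `n_families` founder crosses each producing `fam_size` offspring, plus
#' `n_sports` sport mutants budded from randomly chosen offspring.
#'
#' @param n_founders founders available (named `F1..`).
#' @param n_families number of founder-pair families.
#' @param fam_size full-sib offspring per family.
#' @param n_sports number of sport mutants.
#' @param seed seed for the random sport sources.
#' @return A `pedigree_table` whose founders are the sampled `F*` IDs.
#' @export
script_pedigree <- function(n_founders = 24, n_families = 6, fam_size = 8,
                            n_sports = 2, seed = 1) {
  set.seed(stream_seed(seed, "pedigree"))
  if (2 * n_families > n_founders) stop("not enough founders for families")
  parents <- matrix(paste0("F", sample.int(n_founders, 2 * n_families)),
                    ncol = 2)
  rows <- data.frame(individual = paste0("F", seq_len(n_founders)),
                     sire = NA_character_, dam = NA_character_,
                     relation_type = "cross", stringsAsFactors = FALSE)
  kids <- do.call(rbind, lapply(seq_len(n_families), function(f) {
    data.frame(individual = paste0("Fam", f, "_", seq_len(fam_size)),
               sire = parents[f, 1], dam = parents[f, 2],
               relation_type = "cross", stringsAsFactors = FALSE)
  }))
  rows <- rbind(rows, kids)
  if (n_sports > 0) {
    src <- sample(kids$individual, n_sports)
    rows <- rbind(rows, data.frame(individual = paste0("Sport", seq_len(n_sports)),
                                   sire = src, dam = NA_character_,
                                   relation_type = "sport",
                                   stringsAsFactors = FALSE))
  }
  validate_pedigree(rows)
}
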