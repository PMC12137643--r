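test_that("identical samples yield one segment spanning each chromosome", {
  set.seed(1)
  H1 <- matrix(rbinom(200, 1, 0.4), 2, 100)
  H <- rbind(H1, H1)  # second sample identical
  pos <- c(seq_len(50) * 1000L, seq_len(50) * 1000L)
  x <- make_phased(H, chrom = rep(c("Chr1", "Chr2"), each = 50),
                   pos = pos)
  segs <- call_ibd_segments(x, min_bp = 10000, min_markers = 10)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start, c(1000, 1000))
  expect_equal(segs$end, c(50000, 50000))
})

test_that("unphased input is rejected with guidance", {
  x <- make_snp(matrix(0:1, 2, 10))
  expect_error(call_ibd_segments(x), "RefinedIBD")
})

test_that("gene-dropped truth segments are recovered from error-free data", {
  cfg <- sim_config(n_founders = 12, n_variants = 6000,
                    chrom_lengths = c(Chr1 = 25e6, Chr2 = 25e6),
                    inbred_founder_frac = 0)
  fo <- simulate_founders(cfg, seed = 31)
  ped <- script_pedigree(n_founders = 12, n_families = 2, fam_size = 4,
                         n_sports = 0, seed = 31)
  gd <- gene_drop(fo, ped, cfg, seed = 31)
  min_bp <- 1e6; min_markers <- 120
  pair <- c("Fam1_1", "Fam1_2")
  truth <- truth_ibd(gd, pair[1], pair[2], min_markers = min_markers,
                     min_bp = min_bp)
  called <- call_ibd_segments(subset_snp(gd, samples = pair),
                              min_bp = min_bp, min_markers = min_markers)
  expect_gt(nrow(truth), 0)
  for (i in seq_len(nrow(truth))) {
    cand <- called[called$chrom == truth$chrom[i], , drop = FALSE]
    ov <- pmax(0, pmin(cand$end, truth$end[i]) -
                  pmax(cand$start, truth$start[i]) + 1)
    lt <- truth$end[i] - truth$start[i] + 1
    lc <- cand$end - cand$start + 1
    expect_true(any(ov >= 0.9 * lt & ov >= 0.9 * lc),
                info = paste("truth segment", i, "not recovered"))
  }
})

test_that("unrelated founder pairs rarely share called IBD", {
  frac <- vapply(1:20, function(s) {
    cfg <- sim_config(n_founders = 6, n_variants = 2000,
                      chrom_lengths = c(Chr1 = 20e6, Chr2 = 20e6),
                      inbred_founder_frac = 0)
    fo <- simulate_founders(cfg, seed = s)
    segs <- call_ibd_segments(subset_snp(fo, samples = 1:2),
                              min_bp = 1e6, min_markers = 50)
    if (nrow(segs) == 0) return(0)
    sum(segs$end - segs$start + 1) / 40e6
  }, 0)
  expect_gte(mean(frac < 0.05), 0.95)
})

test_that("pileup counts pairs covering each bin midpoint (brute force)", {
  segs <- data.frame(
    sample_a = c("a", "a", "b"), sample_b = c("b", "c", "c"),
    chrom = "Chr1",
    start = c(1L, 15000L, 18000L), end = c(30000L, 22000L, 60000L),
    score = 1)
  p <- ibd_pileup(segs, c("a", "b", "c"), bin_bp = 10000,
                  chrom_lengths = c(Chr1 = 60000))
  # bin mids 5000.5/15000.5/25000.5/...: a-b covers the first three,
  # a-c covers only 15000.5, b-c covers 25000.5 onward
  expect_equal(p$count, c(1, 2, 2, 1, 1, 1))
  # one segment covering three bins
  p1 <- ibd_pileup(segs[1, ], c("a", "b"), bin_bp = 10000,
                   chrom_lengths = c(Chr1 = 30000))
  expect_equal(p1$count, c(1, 1, 1))
  expect_error(ibd_pileup(segs, "a"), ">= 2")
  # brute-force recount on a random fixture
  set.seed(3)
  rs <- sort(sample.int(90000, 8))
  segs2 <- data.frame(sample_a = "a", sample_b = letters[2:9],
                      chrom = "Chr1", start = rs,
                      end = rs + sample.int(30000, 8), score = 1)
  p2 <- ibd_pileup(segs2, letters[1:9], bin_bp = 5000,
                   chrom_lengths = c(Chr1 = 120000))
  brute <- vapply(p2$mid, function(m)
    sum(segs2$start <= m & segs2$end >= m), 0L)
  expect_equal(p2$count, brute)
})

test_that("shared regions take the top decile of positive bins, merged", {
  pil <- data.frame(chrom = "Chr1",
                    bin_start = seq(1, 91, 10), bin_end = seq(10, 100, 10),
                    mid = seq(5.5, 95.5, 10),
                    count = c(0, 1, 1, 1, 5, 5, 0, 1, 1, 0))
  r <- shared_regions(pil, top_fraction = 0.10, cluster_id = "Clr1")
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(41, 60))  # the two 5-count bins merge
  # uniform positive counts: all positive bins returned
  pil$count <- rep(c(0L, 2L), 5)
  ru <- shared_regions(pil, top_fraction = 0.10)
  expect_equal(sum(ru$end - ru$start + 1), 50)
  # top_fraction = 1 keeps every positive bin
  pil$count <- c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9)
  r1 <- shared_regions(pil, top_fraction = 1)
  expect_equal(sum(r1$end - r1$start + 1), 90)
  # monotone: larger fraction gives a superset of kept bins
  r10 <- shared_regions(pil, top_fraction = 0.10)
  r50 <- shared_regions(pil, top_fraction = 0.50)
  covered <- function(r, p) p >= r$start & p <= r$end
  mids <- pil$mid
  in10 <- vapply(mids, function(m) any(covered(r10, m)), TRUE)
  in50 <- vapply(mids, function(m) any(covered(r50, m)), TRUE)
  expect_true(all(!in10 | in50))
  # all-zero pileup
  pil$count <- 0L
  expect_equal(nrow(shared_regions(pil)), 0)
})

test_that("a common planted segment surfaces in the shared-IBD regions", {
  # ten cluster members copy one founder haplotype over a 200 kb tract
  set.seed(5)
  m <- 500; pos <- sort(sample.int(2e6, m))
  founder_h <- rbinom(m, 1, 0.5)
  H <- matrix(rbinom(20 * m, 1, 0.5), 20, m)
  tract <- which(pos >= 9e5 & pos <= 11e5)
  for (i in 1:10) H[2 * i - 1, tract] <- founder_h[tract]
  x <- make_phased(H, pos = pos)
  segs <- call_ibd_segments(x, min_bp = 5e4, min_markers = 20)
  pil <- ibd_pileup(segs, rownames(x$dosage), bin_bp = 10000,
                    chrom_lengths = c(Chr1 = 2e6))
  reg <- shared_regions(pil, top_fraction = 0.10, cluster_id = "Clr1")
  hit <- any(reg$chrom == "Chr1" & reg$start <= 1e6 & reg$end >= 1e6)
  expect_true(hit)
})

test_that("overlap tables report lengths and Jaccard, omitting disjoint", {
  regions <- data.frame(chrom = "Chr1", start = c(100L, 500L),
                        end = c(200L, 600L))
  iv <- data.frame(chrom = "Chr1", start = c(100L, 150L, 1000L),
                   end = c(200L, 250L, 1100L),
                   name = c("same", "half", "far"))
  ov <- overlap_loci(regions, iv)
  expect_equal(ov$jaccard[ov$interval == "same"], 1)
  expect_equal(ov$overlap_bp[ov$interval == "half"], 51)
  expect_false("far" %in% ov$interval)
})

test_that("pileup mass is conserved against per-segment bin counts", {
  set.seed(8)
  rs <- sort(sample.int(50000, 5))
  segs <- data.frame(sample_a = "a", sample_b = letters[2:6],
                     chrom = "Chr1", start = rs,
                     end = rs + sample.int(20000, 5), score = 1)
  p <- ibd_pileup(segs, letters[1:6], bin_bp = 1000,
                  chrom_lengths = c(Chr1 = 80000))
  per_seg <- vapply(seq_len(nrow(segs)), function(i)
    sum(segs$start[i] <= p$mid & segs$end[i] >= p$mid), 0L)
  expect_equal(sum(p$count), sum(per_seg))
})
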