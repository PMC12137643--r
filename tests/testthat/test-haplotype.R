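test_that("r-squared matches the phased closed form D^2/(p1 q1 p2 q2)", {
  # hand haplotype-count fixture: 10 chromosomes over 2 sites
  # counts: AB 4, Ab 1, aB 1, ab 4  ->  pA = 0.5, pB = 0.5
  hapA <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  hapB <- c(1, 1, 1, 1, 0, 1, 0, 0, 0, 0)
  # D = P(AB) - pA pB = 0.4 - 0.25 = 0.15; r2 = D^2/(pq pq) = 0.36;
  # each gamete enters as a homozygote so the composite (dosage) r2
  # equals the haplotype r2 exactly
  G <- cbind(hapA, hapB)
  H <- G[rep(1:10, each = 2), ]
  storage.mode(H) <- "integer"
  x <- make_phased(H)
  expect_equal(ld_r2(x, 1, 2), 0.36, tolerance = 1e-12)
  # identical dosage vectors give 1
  x2 <- make_snp(cbind(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L)))
  expect_equal(ld_r2(x2, 1, 2), 1)
  # fewer than 3 joint samples gives NA
  D3 <- cbind(c(0L, 1L, NA, NA), c(0L, NA, 1L, 2L))
  expect_true(is.na(ld_r2(make_snp(D3), 1, 2)))
})

test_that("independent variants show near-zero LD at large n", {
  set.seed(4)
  D <- matrix(rbinom(500 * 20, 2, 0.4), 500, 20)
  x <- make_snp(D)
  r2 <- vapply(2:20, function(j) ld_r2(x, 1, j), 0)
  expect_lt(mean(r2), 0.01)
})

# brute-force oracle: all-pairs r2 >= cut over every contiguous interval,
# then the same left-to-right tiling the finder promises
block_oracle <- function(x, cut) {
  m <- n_variants(x)
  ok_pair <- function(i, j) {
    r <- ld_r2(x, i, j)
    !is.na(r) && r >= cut
  }
  valid <- function(a, b) {
    all(vapply(a:(b - 1), function(i)
      all(vapply((i + 1):b, function(j) ok_pair(i, j), TRUE)), TRUE))
  }
  blocks <- list(); i <- 1
  while (i < m) {
    b <- i
    while (b + 1 <= m && valid(i, b + 1)) b <- b + 1
    if (b > i) { blocks[[length(blocks) + 1]] <- c(i, b); i <- b + 1 }
    else i <- i + 1
  }
  blocks
}

test_that("greedy block finder equals the exhaustive oracle on small maps", {
  # perfect LD: one block of 5
  base <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L)
  x <- make_snp(matrix(rep(base, 5), 8, 5))
  b <- find_blocks(x, cut = 0.6)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_snps, 5)
  # impossible cut yields no blocks
  expect_equal(nrow(find_blocks(x, cut = 1.01)), 0)
  # randomized 12-SNP instances vs oracle
  for (s in 1:5) {
    set.seed(s)
    n <- 40
    D <- matrix(0L, n, 12)
    D[, 1] <- rbinom(n, 2, 0.5)
    for (j in 2:12) {
      keep <- rbinom(1, 1, 0.6) == 1
      D[, j] <- if (keep) {
        flip <- runif(n) < 0.1
        ifelse(flip, sample(0:2, n, TRUE), D[, j - 1])
      } else rbinom(n, 2, 0.5)
    }
    x <- make_snp(D)
    got <- find_blocks(x, cut = 0.6)
    want <- block_oracle(x, 0.6)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$first, vapply(want, `[`, 0, 1))
      expect_equal(got$last, vapply(want, `[`, 0, 2))
    }
  }
})

test_that("haplotype construction counts carriers and drops singletons", {
  # planted strings over 3 sites: 5/3/2 accessions, plus one singleton
  s1 <- c(0L, 1L, 0L); s2 <- c(1L, 1L, 1L); s3 <- c(0L, 0L, 1L)
  s4 <- c(1L, 0L, 0L)
  H <- do.call(rbind, c(replicate(5, rbind(s1, s1), simplify = FALSE),
                        replicate(3, rbind(s2, s2), simplify = FALSE),
                        replicate(2, rbind(s3, s3), simplify = FALSE),
                        list(rbind(s4, s4))))
  x <- make_phased(H)
  hs <- build_haplotypes(x, 1:3)
  expect_equal(hs$haplotypes$name, c("Hap1", "Hap2", "Hap3"))
  expect_equal(hs$haplotypes$n_carriers, c(5, 3, 2))
  expect_equal(hs$haplotypes$string, c("010", "111", "001"))
  expect_false("100" %in% hs$haplotypes$string)  # singleton removed
  # uniform panel: one haplotype carried by all
  Hu <- do.call(rbind, replicate(4, rbind(s1, s1), simplify = FALSE))
  hu <- build_haplotypes(make_phased(Hu), 1:3)
  expect_equal(nrow(hu$haplotypes), 1)
  expect_equal(hu$haplotypes$n_carriers, 4)
  # copies with missing alleles are excluded and counted
  Hm <- rbind(s1, s1, s1, c(NA, 1L, 0L))
  Dm <- rbind(2L * s1, s1 + c(NA, 1L, 0L))
  xm <- make_snp(Dm, pos = 1:3 * 1000L)
  xm$phased <- Hm
  hm <- build_haplotypes(xm, 1:3, min_count = 1)
  expect_equal(hm$n_excluded_copies, 1)
})

test_that("two-group LSD equals Student's t and letters separate a shift", {
  set.seed(10)
  s1 <- c(0L, 1L); s2 <- c(1L, 0L)
  H <- do.call(rbind, c(replicate(12, rbind(s1, s1), simplify = FALSE),
                        replicate(12, rbind(s2, s2), simplify = FALSE)))
  x <- make_phased(H)
  hs <- build_haplotypes(x, 1:2)
  vals <- c(rnorm(12, 10), rnorm(12, 10.2))
  ph <- data.frame(accession = hs$samples, trait = "SSC", year = 2016,
                   value = vals)
  res <- haplotype_phenotype_test(hs, ph, "SSC")
  grp <- hap_assign <- res$groups
  tt <- t.test(vals[1:12], vals[13:24], var.equal = TRUE)
  expect_equal(res$pairs$p, tt$p.value, tolerance = 1e-10)
  # planted +2 SD shift separates the letters
  ph2 <- ph; ph2$value <- c(rnorm(12, 10, 1), rnorm(12, 16, 1))
  res2 <- haplotype_phenotype_test(hs, ph2, "SSC")
  expect_true(res2$groups$letter[1] != res2$groups$letter[2])
  expect_lt(res2$anova_p, 0.01)
})

test_that("null haplotype groups are rarely separated", {
  seps <- vapply(1:60, function(s) {
    set.seed(s + 300)
    s1 <- c(0L, 1L); s2 <- c(1L, 0L)
    H <- do.call(rbind, c(replicate(15, rbind(s1, s1), simplify = FALSE),
                          replicate(15, rbind(s2, s2), simplify = FALSE)))
    x <- make_phased(H)
    hs <- build_haplotypes(x, 1:2)
    ph <- data.frame(accession = hs$samples, trait = "SSC", year = 2016,
                     value = rnorm(30))
    res <- haplotype_phenotype_test(hs, ph, "SSC")
    any(res$pairs$p < 0.05)
  }, TRUE)
  expect_lte(mean(seps), 0.15)  # nominal 5% per pair, binomial slack
})

test_that("haplotype network keeps all tied minimal edges and divergence", {
  hs <- list(haplotypes = data.frame(
    name = c("Hap1", "Hap2", "Hap3"),
    string = c("0000", "0001", "0011"),
    n_carriers = c(5, 3, 2), n_copies = c(10, 6, 4)),
    samples = character(0))
  class(hs) <- "haplotype_set"
  net <- haplotype_network(hs)
  # collinear strings: A-B 1, B-C 1, A-C 2 -> only the two unit edges
  expect_equal(nrow(net), 2)
  expect_true(all(net$weight == 1))
  expect_false(any(net$from == "Hap1" & net$to == "Hap3"))
  # two haplotypes differing at one site: single edge of weight 1
  hs2 <- hs; hs2$haplotypes <- hs$haplotypes[1:2, ]
  net2 <- haplotype_network(hs2)
  expect_equal(net2$weight, 1)
  # divergence: 19/20 sites differ -> 95% altered
  hs3 <- list(haplotypes = data.frame(
    name = c("Hap1", "Hap2"),
    string = c(strrep("0", 20),
               paste0(strrep("1", 19), "0")),
    n_carriers = c(2, 2), n_copies = c(4, 4)), samples = character(0))
  class(hs3) <- "haplotype_set"
  dv <- attr(haplotype_network(hs3), "divergence")
  expect_equal(unname(dv["Hap2"]), 95.0)
})

test_that("tied minimum spanning edges are all retained", {
  # square: four strings pairwise distance 2 around a cycle, diagonals 4
  hs <- list(haplotypes = data.frame(
    name = paste0("Hap", 1:4),
    string = c("0000", "0011", "1111", "1100"),
    n_carriers = 2:5, n_copies = 2:5), samples = character(0))
  class(hs) <- "haplotype_set"
  net <- haplotype_network(hs)
  # all four side edges are in some MST; the diagonals are not
  expect_equal(nrow(net), 4)
  expect_true(all(net$weight == 2))
})

test_that("cluster haplotype frequencies sum to one and match hand tally", {
  s1 <- c(0L, 1L); s2 <- c(1L, 0L)
  # acc1-2: hom Hap1; acc3: het Hap1/Hap2; acc4-5: hom Hap2
  H <- rbind(s1, s1, s1, s1, s1, s2, s2, s2, s2, s2)
  x <- make_phased(H)
  hs <- build_haplotypes(x, 1:2)
  clusters <- list(ClrA = c("S1", "S2", "S3"), ClrB = c("S4", "S5"))
  fr <- cluster_haplotype_freq(hs, clusters)
  expect_equal(rowSums(fr), c(ClrA = 1, ClrB = 1))
  h1 <- hs$haplotypes$name[hs$haplotypes$string == "01"]
  h2 <- hs$haplotypes$name[hs$haplotypes$string == "10"]
  expect_equal(fr["ClrA", h1], 2.5 / 3)  # two hom + half of the het
  expect_equal(fr["ClrA", h2], 0.5 / 3)
  expect_equal(fr["ClrB", h2], 1)
})
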