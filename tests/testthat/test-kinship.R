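test_that("GRM treats duplicate samples as self and is permutation-equivariant", {
  set.seed(1)
  D <- matrix(rbinom(50 * 200, 2, runif(200, 0.1, 0.5)), 50, 200,
              byrow = TRUE)
  rownames(D) <- paste0("s", 1:50)
  D[2, ] <- D[1, ]  # duplicate sample
  K <- grm(D)
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])
  expect_true(isSymmetric(K))
  # permutation equivariance
  perm <- sample(1:50)
  K2 <- grm(D[perm, ])
  expect_equal(K2[rownames(D), rownames(D)], K, tolerance = 1e-12,
               ignore_attr = TRUE)
  # centering property: every row of K sums to ~0, so the mean
  # off-diagonal of an independent panel is -mean(diag)/(n-1) -> ~0
  expect_lt(max(abs(rowSums(K))), 1e-8)
  off <- K[upper.tri(K)]
  expect_equal(mean(off), -mean(diag(K)) / (nrow(K) - 1),
               tolerance = 1e-10)
  expect_lt(abs(mean(off)), 0.05)
})

test_that("pedigree kinship gives the textbook base cases", {
  ped <- simple_pedigree()
  K <- pedigree_kinship(ped)
  expect_equal(K["A", "A"], 1)      # non-inbred founder self
  expect_equal(K["A", "B"], 0)      # unrelated founders
  expect_equal(K["C", "A"], 0.5)    # parent-offspring
  expect_equal(K["C", "C"], 1)      # offspring of unrelated parents

  # full sibs 0.5; selfed offspring has F = 0.5, self = 1.5
  ped2 <- validate_pedigree(data.frame(
    individual = c("A", "B", "C", "D", "S"),
    sire = c(NA, NA, "A", "A", "C"),
    dam = c(NA, NA, "B", "B", "C"),
    relation_type = "cross", stringsAsFactors = FALSE))
  K2 <- pedigree_kinship(ped2)
  expect_equal(K2["C", "D"], 0.5)
  expect_equal(K2["S", "S"], 1.5)
})

test_that("sport pairs carry the configured near-self relatedness", {
  ped <- validate_pedigree(data.frame(
    individual = c("A", "B", "C", "Sp"),
    sire = c(NA, NA, "A", "C"),
    dam = c(NA, NA, "B", NA),
    relation_type = c("cross", "cross", "cross", "sport"),
    stringsAsFactors = FALSE))
  K <- pedigree_kinship(ped)
  expect_equal(K["Sp", "C"], 0.97)
  # clone semantics elsewhere: sport relates to C's parents like C does
  expect_equal(K["Sp", "A"], K["C", "A"])
  K9 <- pedigree_kinship(ped, sport_value = 0.9)
  expect_equal(K9["Sp", "C"], 0.9)
})

test_that("recursive kinship matches Monte-Carlo gene dropping", {
  # 10-member pedigree with inbreeding (half sibs, cousin cross, selfing)
  ped <- validate_pedigree(data.frame(
    individual = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J"),
    sire = c(NA, NA, NA, "A", "A", "B", "D", "E", "G", "I"),
    dam  = c(NA, NA, NA, "B", "C", "C", "E", "F", "H", "I"),
    relation_type = "cross", stringsAsFactors = FALSE))
  K <- pedigree_kinship(ped)
  Kmc <- kinship_mc(ped, n_rep = 10000, seed = 42)
  expect_lt(max(abs(K - Kmc[rownames(K), colnames(K)])), 0.02)
})

test_that("kinship correlation handles identity and degenerate input", {
  set.seed(2)
  K <- matrix(runif(25), 5, 5); K <- (K + t(K)) / 2
  dimnames(K) <- list(letters[1:5], letters[1:5])
  pairs <- data.frame(a = c("a", "a", "b", "c"), b = c("b", "c", "d", "e"))
  r <- kinship_correlation(K, K, pairs)
  expect_equal(r$r, 1)
  Kc <- K; Kc[] <- 0.3
  expect_error(kinship_correlation(K, Kc, pairs), "degenerate")
  expect_error(kinship_correlation(K, K, pairs[1:2, ]), ">= 3")
})

test_that("inbreeding F hits the analytic extremes and selfing theory", {
  # panel with allele frequency 0.5 everywhere
  D <- rbind(hom = rep(c(0L, 2L), 50),
             het = rep(1L, 100),
             filler1 = rep(c(0L, 2L), 50),
             filler2 = rep(c(2L, 0L), 50),
             filler3 = rep(c(2L, 0L), 50))  # balances every site at p = 0.5
  f <- inbreeding_f(make_snp(D))
  expect_equal(unname(f["hom"]), 1)
  expect_equal(unname(f["het"]), -1)

  # three generations of selfing: E[F] = 1 - (1/2)^3 = 0.875
  cfg <- sim_config(n_founders = 40, n_variants = 3000,
                    chrom_lengths = c(Chr1 = 30e6, Chr2 = 30e6),
                    inbred_founder_frac = 0)
  fo <- simulate_founders(cfg, seed = 21)
  ped <- data.frame(individual = paste0("F", 1:40), sire = NA,
                    dam = NA, relation_type = "cross",
                    stringsAsFactors = FALSE)
  prev <- paste0("F", 1:20)
  for (g in 1:3) {
    cur <- paste0("G", g, "_", seq_along(prev))
    ped <- rbind(ped, data.frame(individual = cur, sire = prev,
                                 dam = prev, relation_type = "cross"))
    prev <- cur
  }
  gd <- suppressWarnings(gene_drop(fo, validate_pedigree(ped), cfg,
                                   seed = 21))
  f3 <- inbreeding_f(gd)[prev]
  expect_lt(abs(mean(f3) - 0.875), 0.05)
})

test_that("network clustering equals connected components above threshold", {
  ids <- paste0("s", 1:8)
  K <- matrix(0, 8, 8, dimnames = list(ids, ids))
  diag(K) <- 1
  # complete triangle at 0.6
  K[1, 2] <- K[2, 1] <- K[1, 3] <- K[3, 1] <- K[2, 3] <- K[3, 2] <- 0.6
  # a pair exactly at the threshold: strict > means no edge
  K[4, 5] <- K[5, 4] <- 0.45
  # an isolated pair above threshold
  K[6, 7] <- K[7, 6] <- 0.5
  net <- kinship_network(K, threshold = 0.45, min_cluster = 3)
  expect_length(net$clusters, 1)
  expect_setequal(net$clusters[[1]]$members, ids[1:3])
  expect_equal(unname(net$clusters[[1]]$degree), c(2, 2, 2))
  expect_setequal(net$small, ids[6:7])        # isolated pair reported apart
  expect_true(all(ids[c(4, 5, 8)] %in% net$unconnected))

  # oracle: components of the thresholded graph via exhaustive DFS
  set.seed(5)
  A <- matrix(runif(100), 10, 10); A <- (A + t(A)) / 2
  dimnames(A) <- list(paste0("x", 1:10), paste0("x", 1:10))
  net2 <- kinship_network(A, threshold = 0.7, min_cluster = 2)
  adj <- A > 0.7; diag(adj) <- FALSE
  dfs_comp <- function(adj) {
    n <- nrow(adj); seen <- rep(FALSE, n); comp <- integer(n); c0 <- 0
    for (s in 1:n) {
      if (seen[s]) next
      c0 <- c0 + 1; stack <- s
      while (length(stack)) {
        v <- stack[[1]]; stack <- stack[-1]
        if (seen[v]) next
        seen[v] <- TRUE; comp[v] <- c0
        stack <- c(stack, which(adj[v, ] & !seen))
      }
    }
    comp
  }
  comp <- dfs_comp(adj)
  got <- lapply(net2$clusters, function(cl) sort(cl$members))
  want <- Filter(function(m) length(m) >= 2,
                 lapply(split(rownames(A), comp), sort))
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, paste, "", collapse = ","))
})

test_that("simulated families are recovered as clusters from the GRM", {
  # four 10-offspring families inside a diverse panel, generator defaults
  # (partially inbred founders, full 8-chromosome map)
  hits <- vapply(1:30, function(s) {
    cfg <- sim_config(n_founders = 200, n_variants = 3000)
    fo <- simulate_founders(cfg, seed = s)
    ped <- script_pedigree(n_founders = 200, n_families = 4,
                           fam_size = 10, n_sports = 0, seed = s)
    gd <- gene_drop(fo, ped, cfg, seed = s)
    K <- grm(gd)  # allele frequencies from the whole diverse panel
    kids <- grep("^Fam", rownames(gd$dosage), value = TRUE)
    net <- kinship_network(K[kids, kids], threshold = 0.45,
                           min_cluster = 3)
    if (length(net$clusters) != 4) return(FALSE)
    all(vapply(net$clusters, function(cl)
      length(unique(sub("_.*", "", cl$members))) == 1 &&
        length(cl$members) == 10, TRUE))
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("cluster shares render like the published table", {
  clusters <- list(list(cluster_id = "Clr1", members = paste0("a", 1:59)),
                   list(cluster_id = "Clr2", members = paste0("b", 1:142)))
  cs <- cluster_share(clusters)
  expect_equal(cs$share[1], "29.35%")
  one <- cluster_share(list(list(cluster_id = "Clr1", members = "x")))
  expect_equal(one$share, "100.00%")
  expect_equal(nrow(cluster_share(list())), 0)
})
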