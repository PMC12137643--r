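#!/usr/bin/env Rscript
# SNP-based and pedigree-based kinship, their correlation over known
# pedigree pairs, per-accession inbreeding, and threshold network
# clustering of the panel.

suppressPackageStartupMessages(library(orchardpop))
dir.create("results", showWarnings = FALSE)

panel <- read_vcf("results/simdata/panel_clean.vcf", want_phase = TRUE)
ped <- read_pedigree("results/simdata/pedigree.csv")

K_snp <- grm(panel)
K_ped <- pedigree_kinship(ped)
utils::write.table(round(K_snp, 4), "results/kinship_snp.tsv",
                   sep = "\t", quote = FALSE)

# correlate over a mix of recorded relationships: parent-offspring,
# full sibs, sport pairs, and cross-family (unrelated) pairs
kids <- ped$individual[!is.na(ped$sire) & ped$relation_type == "cross"]
po <- data.frame(a = kids, b = ped$sire[match(kids, ped$individual)])
fs <- do.call(rbind, lapply(split(kids, sub("_.*", "", kids)), function(k)
  if (length(k) >= 2) as.data.frame(t(utils::combn(k, 2)))))
names(fs) <- c("a", "b")
sports <- ped$individual[ped$relation_type == "sport"]
sp <- data.frame(a = sports,
                 b = ifelse(is.na(ped$sire[match(sports, ped$individual)]),
                            ped$dam[match(sports, ped$individual)],
                            ped$sire[match(sports, ped$individual)]))
set.seed(1)
fam_of <- sub("_.*", "", kids)
xf <- do.call(rbind, lapply(1:120, function(i) {
  k2 <- sample(kids, 2)
  if (fam_of[match(k2[1], kids)] != fam_of[match(k2[2], kids)])
    data.frame(a = k2[1], b = k2[2])
}))
pairs <- unique(rbind(po, fs, sp, xf))
r <- kinship_correlation(K_snp, K_ped, pairs)
message(sprintf("SNP vs pedigree kinship over %d known pairs: r = %.2f (p = %.2g)",
                r$n, r$r, r$p))

fvals <- inbreeding_f(panel)
founder_f <- fvals[grep("^F", names(fvals))]
message(sprintf("inbreeding: founder mean F = %.3f; offspring mean F = %.3f",
                mean(founder_f), mean(fvals[grep("^Fam", names(fvals))])))

net <- kinship_network(K_snp, threshold = 0.45, min_cluster = 3)
message(length(net$clusters), " multi-member clusters; ",
        length(net$small), " accessions in isolated pairs/small groups; ",
        length(net$unconnected), " unconnected")
print(cluster_share(net$clusters))

# sport pairs sit near the self value in the SNP kinship
sports <- ped$individual[ped$relation_type == "sport"]
if (length(sports)) {
  src <- ifelse(is.na(ped$sire[match(sports, ped$individual)]),
                ped$dam[match(sports, ped$individual)],
                ped$sire[match(sports, ped$individual)])
  message("sport/source SNP relatedness: ",
          paste(sprintf("%.3f", K_snp[cbind(sports, src)]),
                collapse = ", "),
          " (pedigree convention assigns ",
          K_ped[cbind(sports, src)][1], ")")
}
utils::write.table(net$membership, "results/kinship_clusters.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
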