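#!/usr/bin/env Rscript
# IBD segments within each kinship cluster (IBS-run stand-in caller on
# the phased panel) and the shared-IBD regions: top decile of the
# per-bin pair-coverage pileup, merged.

suppressPackageStartupMessages(library(orchardpop))
dir.create("results", showWarnings = FALSE)

panel <- read_vcf("results/simdata/panel_clean.vcf", want_phase = TRUE)
truth <- readRDS("results/simdata/truth_internal.rds")
clusters <- utils::read.delim("results/kinship_clusters.tsv")
chrom_lengths <- truth$cfg$chrom_lengths

all_regions <- list()
for (cl in unique(clusters$cluster)) {
  members <- clusters$member[clusters$cluster == cl]
  if (length(members) < 2) next
  segs <- call_ibd_segments(subset_snp(panel, samples = members),
                            min_bp = 1e6, min_markers = 40)
  pil <- ibd_pileup(segs, members, bin_bp = 10000,
                    chrom_lengths = chrom_lengths)
  reg <- shared_regions(pil, top_fraction = 0.10, cluster_id = cl)
  message(cl, ": ", length(members), " members, ", nrow(segs),
          " IBD segments, ", nrow(reg), " shared regions (threshold ",
          if (nrow(reg)) reg$threshold[1] else NA, " pairs)")
  all_regions[[cl]] <- reg
}
regions <- do.call(rbind, all_regions)
utils::write.table(regions, "results/shared_ibd_regions.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

# do the planted QTLs fall inside any cluster's shared IBD regions?
qtl <- utils::read.delim("results/simdata/qtl_truth.tsv")
ov <- overlap_loci(regions,
                   data.frame(chrom = qtl$chrom, start = qtl$pos - 5e4,
                              end = qtl$pos + 5e4, name = qtl$trait))
if (nrow(ov)) {
  message("QTLs inside shared IBD regions:")
  print(ov)
} else message("no QTL falls inside a shared IBD region in this panel")
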