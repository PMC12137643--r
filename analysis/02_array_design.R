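#!/usr/bin/env Rscript
# The staged SNP-selection cascade on the degraded call set: quality
# control, shared-variant rule, performance categories on a genotyping
# panel, legacy-array integration, and the funnel report with interval
# statistics.

suppressPackageStartupMessages(library(orchardpop))
dir.create("results", showWarnings = FALSE)

x <- read_vcf("results/simdata/panel_degraded.vcf")
n0 <- n_variants(x)

qc <- qc_filter(x)
message("QC: ", sum(qc$keep), "/", n0, " variants pass ",
        "(failures by criterion: ",
        paste(names(qc$report)[1:4], qc$report[1:4], collapse = ", "), ")")

sv <- shared_variant_filter(qc$data)
cats <- classify_performance(sv$data)
message("performance categories:")
print(table(cats))
final <- subset_snp(sv$data, variants = which(select_final(cats)))

# a legacy lower-density array: every 9th surviving position plus some
# novel positions beyond the panel
legacy <- rbind(final$variants[seq(1, n_variants(final), 9),
                               c("chrom", "pos")],
                data.frame(chrom = "Chr1",
                           pos = seq(27e6, 27.9e6, by = 3000)))
integ <- integrate_legacy(final$variants[, c("chrom", "pos")], legacy)
message("integration: ", integ$n_final, " + ", integ$n_legacy, " - ",
        integ$n_overlap, " overlap = ", integ$n_merged, " merged")

funnel <- funnel_report(c(candidates = n0,
                          qc_pass = sum(qc$keep),
                          shared2 = n_variants(sv$data),
                          final_categories = n_variants(final),
                          with_legacy = integ$n_merged),
                        final_count = integ$n_merged)
print(funnel)
utils::write.table(funnel, "results/funnel_report.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

iv <- interval_stats(integ$merged)
message(sprintf("merged set: mean SNP interval %.0f bp; 90th pct %.0f bp; %.1f%% of SNPs have a neighbor within 3 kb",
                iv$mean_gap, iv$percentiles["p90"],
                100 * iv$frac_with_neighbor))

# concordance of the degraded calls against simulation truth
truth <- readRDS("results/simdata/truth_internal.rds")
clean <- read_vcf("results/simdata/panel_clean.vcf")
conc <- genotype_concordance(x$dosage, clean$dosage)
message(sprintf("degraded-vs-true genotype concordance: %.2f%% (missing: degraded %.2f%%, clean %.2f%%)",
                100 * conc$overall, 100 * conc$missing_a,
                100 * conc$missing_b))
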