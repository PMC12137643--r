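#!/usr/bin/env Rscript
# Generate the synthetic orchard panel used by the downstream analyses:
# a multi-family, partially inbred accession collection with sport
# mutants, planted QTLs (flowering, titratable acidity, citrate), and
# genotyping artifacts. Writes VCF + pedigree CSV + phenotype TSV under
# results/simdata/.

suppressPackageStartupMessages(library(orchardpop))
seed <- 42
dir.create("results/simdata", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_founders = 120, n_variants = 8000)
founders <- simulate_founders(cfg, seed = seed)
ped <- script_pedigree(n_founders = 120, n_families = 6, fam_size = 10,
                       n_sports = 3, seed = seed)
panel <- suppressWarnings(gene_drop(founders, ped, cfg, seed = seed))
message("panel: ", n_samples(panel), " accessions x ",
        n_variants(panel), " SNPs (",
        sum(ped$relation_type == "sport"), " sports)")

pheno <- rbind(simulate_phenotypes(panel, cfg, seed = seed, year = 2016),
               simulate_phenotypes(panel, cfg, seed = seed + 1,
                                   year = 2017))
truth <- attr(simulate_phenotypes(panel, cfg, seed = seed), "truth")
message("planted QTLs (realized variance shares):")
print(truth[, c("trait", "chrom", "pos", "target_pve", "realized_pve")])

degraded <- degrade_calls(panel, cfg, seed = seed)

write_vcf(panel, "results/simdata/panel_clean.vcf")
write_vcf(degraded, "results/simdata/panel_degraded.vcf")
utils::write.csv(as.data.frame(ped), "results/simdata/pedigree.csv",
                 row.names = FALSE, quote = FALSE, na = "")
utils::write.table(pheno, "results/simdata/phenotypes.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
utils::write.table(truth, "results/simdata/qtl_truth.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
saveRDS(list(cfg = cfg, seed = seed,
             origin = attr(panel, "origin"),
             samples = rownames(panel$dosage),
             variants = panel$variants),
        "results/simdata/truth_internal.rds")
message("wrote results/simdata/ (clean + degraded VCF, pedigree, ",
        "phenotypes, QTL truth)")
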