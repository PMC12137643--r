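#!/usr/bin/env Rscript
# Descriptive trait statistics: sugar-component ratios, Spearman
# correlation matrix with significance mask, flowering-date
# distribution, and cluster-vs-rest phenotype tests.

suppressPackageStartupMessages(library(orchardpop))
dir.create("results", showWarnings = FALSE)

pheno <- read_phenotypes("results/simdata/phenotypes.tsv")
cl <- utils::read.delim("results/kinship_clusters.tsv")

ts <- trait_summary(pheno, year = 2016)
message("sugar proportions (sucrose:glucose:fructose:sorbitol) = ",
        ts$ratio_string)
message("malate/citrate ratio range: ",
        paste(ts$malate_citrate_range, collapse = " to "))

traits <- c("SSC", "pH", "TA", "sucrose", "glucose", "fructose",
            "sorbitol", "malate", "citrate")
traits <- intersect(traits, unique(pheno$trait))
sm <- spearman_matrix(pheno, traits, year = 2016)
utils::write.table(round(sm$rho, 3), "results/spearman_rho.tsv",
                   sep = "\t", quote = FALSE)
message("Spearman matrix over ", length(traits), " traits written; ",
        sum(sm$not_significant[upper.tri(sm$rho)], na.rm = TRUE),
        " pairs masked at p >= 0.05")

fd <- flowering_distribution(pheno, year = 2016)
message(sprintf("flowering: peak day %d with %.2f%% of accessions; span %d days",
                fd$peak_day, fd$peak_share_pct, fd$span_days))

for (clu in unique(cl$cluster)) {
  members <- cl$member[cl$cluster == clu]
  for (tr in c("TA", "citrate", "flowering_date")) {
    r <- tryCatch(cluster_vs_rest(pheno, tr, members, year = 2016),
                  error = function(e) NULL)
    if (!is.null(r) && r$p < 0.05) {
      message(sprintf("%s differs in %s (%s, p = %.2g): %.2f vs %.2f",
                      tr, clu, r$test, r$p, r$mean_cluster, r$mean_rest))
    }
  }
}
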