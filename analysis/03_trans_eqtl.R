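#!/usr/bin/env Rscript
# Step 3 - trans scan of the lead variant against every expressed gene in
# the LPS condition: per-gene inverse-normal transform, population-adjusted
# OLS, Benjamini-Hochberg FDR at 1%, and the |beta| >= 0.2 effect filter.

suppressPackageStartupMessages(library(fireqtl))
truth <- jsonlite::read_json("results/simulation_truth.json",
                             simplifyVector = TRUE)
lead <- jsonlite::read_json("results/cis_summary.json",
                            simplifyVector = TRUE)$lead_snp
pops <- readLines("results/cohort_populations.txt")
geno <- read_vcf("results/cohort_genotypes.vcf", population = pops)$genotypes
expr <- read_expression("results/cohort_expression.tsv")

message("Testing ", lead, " against ", length(expr$genes),
        " genes (LPS condition) ...")
tr <- map_trans_eqtl(geno, lead, expr, condition = "LPS",
                     fdr = 0.01, min_abs_beta = 0.2)
write.table(tr$all, "results/trans_eqtl_all.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(tr$hits, "results/trans_eqtl_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("  associations at FDR 1% and |beta| >= 0.2: ", nrow(tr$hits))
if (nrow(tr$hits)) {
  message(sprintf("  %.0f%% of hits are down-regulated by the derived allele",
                  100 * mean(tr$hits$direction == "down")))
  message("  top hit: ", tr$hits$gene[which.min(tr$hits$q)],
          " (the planted cis target is ", truth$target_gene, ")")
}
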