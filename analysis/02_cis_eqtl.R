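#!/usr/bin/env Rscript
# Step 2 - cis-eQTL mapping of the target gene: inverse-normal transform per
# condition, OLS with a population covariate for every SNP x condition pair,
# a 1%-FWER significance threshold from 1000 within-population permutations,
# and a conditional scan on the lead variant.

suppressPackageStartupMessages(library(fireqtl))
truth <- jsonlite::read_json("results/simulation_truth.json",
                             simplifyVector = TRUE)
pops <- readLines("results/cohort_populations.txt")
geno <- read_vcf("results/cohort_genotypes.vcf", population = pops)$genotypes
expr <- read_expression("results/cohort_expression.tsv")

message("Scanning ", nrow(geno$variants), " SNPs x ",
        length(unique(expr$condition)), " conditions for ",
        truth$target_gene, " ...")
cis <- map_cis_eqtl(geno, expr, truth$target_gene)
cal <- permutation_fwer_threshold(geno, expr, truth$target_gene,
                                  n_permutations = 1000, target_fwer = 0.01,
                                  seed = 20200918)
cis$significant <- cis$p < cal$threshold
lead <- cis$snp[which.min(cis$p)]
write.table(cis, "results/cis_eqtl.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("  FWER threshold (1%%, 1000 permutations): p < %.3g",
                cal$threshold))
message(sprintf("  lead variant: %s (p = %.3g, partial R2 = %.1f%%) - %s",
                lead, min(cis$p), 100 * cis$r2[which.min(cis$p)],
                ifelse(lead == truth$causal_snp,
                       "the planted causal variant", "NOT the planted one")))
message("  significant SNP x condition pairs: ", sum(cis$significant))

cond <- conditional_scan(geno, expr, truth$target_gene, condition_on = lead)
write.table(cond, "results/cis_eqtl_conditional.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("  after conditioning on ", lead, ": ",
        sum(cond$p < cal$threshold),
        " significant associations remain")
jsonlite::write_json(list(lead_snp = lead, lead_p = min(cis$p),
                          fwer_threshold = cal$threshold,
                          n_significant = sum(cis$significant),
                          n_significant_conditional =
                            sum(cond$p < cal$threshold)),
                     "results/cis_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
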