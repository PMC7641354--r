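#!/usr/bin/env Rscript
# Step 5 - selection scan around the focal site: Tajima's D in the 100-kb
# window, Weir-Cockerham F_ST between the cohort populations, and EHH/iHS
# with 40-bin DAF standardization, each summarized as a rank-based
# empirical p-value against the other sites (the chromosome-wide reference
# at full-data scale).

suppressPackageStartupMessages(library(fireqtl))
neutral <- read_vcf("results/haplotypes_neutral.vcf")$haplotypes
swept <- read_vcf("results/haplotypes_sweep.vcf")$haplotypes
focal_bp <- as.numeric(readLines("results/sweep_focal_bp.txt"))
focal <- which(swept$positions == focal_bp)

taj_n <- tajimas_d(neutral)
taj_s <- tajimas_d(swept, window = focal_bp + c(-5e4, 5e4))
message(sprintf("Tajima's D: neutral panel %.2f, sweep panel %.2f",
                taj_n$D, taj_s$D))

message("Computing unstandardized iHS at every eligible site ...")
scan_ihs <- function(haps) {
  elig <- which(haps$daf >= 0.05 & haps$daf <= 0.95)
  do.call(rbind, lapply(elig, function(j) {
    u <- ihs_unstandardized(haps, j)
    data.frame(site = j, position = u$position, daf = u$daf, uihs = u$uihs)
  }))
}
# DAF-bin standardization needs a dense neutral reference (at full-data
# scale, all chromosome sites); pool the saved neutral panel with further
# neutral replicates so every occupied bin has enough sites
message("  building the pooled neutral iHS reference (30 panels) ...")
ref_tab <- rbind(scan_ihs(neutral),
                 do.call(rbind, lapply(1:29, function(s)
                   scan_ihs(simulate_haplotypes(
                     hap_sim_spec(seed = 20200921 + s))))))
std_ref <- ihs_standardize(ref_tab, n_bins = 40, daf_range = c(0.05, 0.95))
foc_tab <- scan_ihs(swept)
std_foc <- ihs_standardize(foc_tab, n_bins = 40, daf_range = c(0.05, 0.95),
                           bin_stats = attr(std_ref, "bin_stats"))
write.table(std_foc, "results/ihs_sweep_panel.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
z <- std_foc$ihs[std_foc$site == focal]
emp_ihs <- empirical_pvalue(z, std_ref$ihs[!is.na(std_ref$ihs)],
                            tail = "abs")
message(sprintf("  focal |iHS| = %.2f, empirical p = %.3f (neutral reference, N = %d)",
                abs(z), emp_ihs$p_emp, emp_ihs$N))

# F_ST uses the two-population cohort genotypes
pops <- readLines("results/cohort_populations.txt")
geno <- read_vcf("results/cohort_genotypes.vcf", population = pops)$genotypes
lead <- jsonlite::read_json("results/cis_summary.json",
                            simplifyVector = TRUE)$lead_snp
fst <- fst_amova(geno)
j <- match(lead, fst$per_site$id)
emp_fst <- empirical_pvalue(fst$per_site$fst[j], fst$per_site$fst[-j])
message(sprintf("F_ST: global %.3f; at %s %.3f (empirical p = %.2f)",
                fst$global, lead, fst$per_site$fst[j], emp_fst$p_emp))

jsonlite::write_json(list(tajima_neutral = taj_n$D, tajima_sweep = taj_s$D,
                          focal_abs_ihs = abs(z),
                          focal_ihs_p_emp = emp_ihs$p_emp,
                          global_fst = fst$global,
                          lead_fst = fst$per_site$fst[j],
                          lead_fst_p_emp = emp_fst$p_emp),
                     "results/selection_summary.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
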