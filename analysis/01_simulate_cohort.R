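#!/usr/bin/env Rscript
# Step 1 - build the synthetic study inputs with known ground truth:
# a two-population monocyte eQTL cohort (genotypes + expression) with one
# planted cis-regulatory variant, phased haplotype panels (neutral and
# partial-sweep) for the selection scan, and a 46-way ortholog alignment
# carrying a C/EBP-like binding site at the focal position.
# Everything is written to results/ in standard formats (VCF, TSV, MAF).

suppressPackageStartupMessages(library(fireqtl))
dir.create("results", showWarnings = FALSE)
SEED <- 20200917

message("Simulating the eQTL cohort (2 x 100 individuals, 500 SNPs) ...")
eqtl <- simulate_eqtl_dataset(eqtl_sim_spec(seed = SEED))
write_vcf(eqtl$genotypes, "results/cohort_genotypes.vcf")
write_expression(eqtl$expression, "results/cohort_expression.tsv")
writeLines(eqtl$genotypes$population, "results/cohort_populations.txt")
jsonlite::write_json(eqtl$truth, "results/simulation_truth.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("  causal variant: ", eqtl$truth$causal_snp,
        sprintf(" (MAF %.2f, planted beta %.2f)",
                eqtl$truth$causal_maf, eqtl$truth$beta_cis))

message("Simulating haplotype panels (Wright-Fisher, 100 kb) ...")
neutral <- simulate_haplotypes(hap_sim_spec(seed = SEED + 1))
write_vcf(neutral, "results/haplotypes_neutral.vcf")
sweep <- simulate_haplotypes(hap_sim_spec(
  sweep = list(site_position = 5e4, selection_coefficient = 0.25,
               final_frequency = 0.7), seed = SEED + 2))
write_vcf(sweep, "results/haplotypes_sweep.vcf")
writeLines(as.character(sweep$focal_position), "results/sweep_focal_bp.txt")
message(sprintf("  neutral: %d segregating sites; sweep: focal DAF %.2f after %d restart(s)",
                ncol(neutral$haplotypes), sweep$daf[sweep$focal_site],
                sweep$sweep_restarts))

message("Simulating the 46-way ortholog alignment ...")
# focal column on the variable adenine (8th base) of the TTTGTCAAC site,
# planted in 30 of 46 species
aln <- simulate_ortholog_alignment(aln_sim_spec(
  n_species = 46, n_species_with_motif = 30, motif_offset = -7,
  seed = SEED + 3))
write_maf(aln, "results/ortholog_alignment.maf")
writeLines(as.character(aln$focal_column - 1L), "results/alignment_focal.txt")
message("  wrote results/ortholog_alignment.maf (ref species ",
        aln$ref_species, ")")
message("Done.")
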