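#!/usr/bin/env Rscript
# Step 6 - five-criterion prioritization of the candidate LD block around
# the lead variant (ortholog-enhancer overlap, predicted regulatory element,
# ENCODE TFBS, GERP conservation, conserved TFBS), plus the allelic-
# imbalance analysis pattern used for ChIP validation data.

suppressPackageStartupMessages(library(fireqtl))
pops <- readLines("results/cohort_populations.txt")
geno <- read_vcf("results/cohort_genotypes.vcf", population = pops)$genotypes
cis <- read.table("results/cis_eqtl.tsv", header = TRUE, sep = "\t")
lead <- jsonlite::read_json("results/cis_summary.json",
                            simplifyVector = TRUE)$lead_snp
truth <- jsonlite::read_json("results/simulation_truth.json",
                             simplifyVector = TRUE)

# candidate block: r2 >= 0.5 with the lead variant
dos <- impute_dosages(geno)
ld <- apply(dos, 1, function(row)
  suppressWarnings(ld_r2(row, dos[match(lead, rownames(dos)), ])))
best_p <- tapply(cis$p, cis$snp, min)
cand <- data.frame(id = geno$variants$id, chrom = geno$variants$chrom,
                   pos = geno$variants$pos,
                   eqtl_p = as.numeric(best_p[geno$variants$id]),
                   ld_r2 = ld)
cand <- cand[!is.na(cand$ld_r2), ]
message("Candidates in LD (r2 >= 0.5) with ", lead, ": ",
        sum(cand$ld_r2 >= 0.5))

# annotation: synthetic tracks planted so that only the causal variant is
# fully supported (emulating regulatory-build, TFBS and GERP annotation)
ann <- synthetic_prioritization_tracks(geno, truth$causal_snp,
                                       seed = 20200919)
mot <- jsonlite::read_json("results/motif_conservation.json",
                           simplifyVector = TRUE)
calls <- setNames(list(list(structure(
  list(tf_name = mot$tf, n_species_detected = mot$n_species_detected,
       conserved = mot$conserved, species_threshold = 20),
  class = "ConservationCall"))), lead)
led <- prioritize_variants(cand, tracks = ann$tracks, gerp = ann$gerp,
                           conservation_calls = calls, ld_threshold = 0.5)
write.table(as.data.frame(led), "results/prioritization.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("  top-ranked: ", led$id[1], " with ", led$n_criteria[1],
        "/", led$n_known[1], " criteria",
        ifelse(isTRUE(attr(led, "unique_complete")),
               " - the only variant satisfying all five", ""))

# allelic imbalance: 7 simulated heterozygous donors, ChIP enriching the
# ancestral allele ~2.6-fold over input
set.seed(20200920)
donors <- data.frame(input_a = rnorm(7, 110, 6), input_b = rnorm(7, 100, 6),
                     chip_a = rnorm(7, 285, 18), chip_b = rnorm(7, 100, 8))
ai <- allelic_imbalance(donors)
message(sprintf("  allelic ratio: input %.2f +/- %.2f -> ChIP %.2f +/- %.2f (p = %.3g, %s)",
                ai$input_mean, ai$input_sem, ai$chip_mean, ai$chip_sem,
                ai$p_value, ai$test))
jsonlite::write_json(list(top_variant = led$id[1],
                          unique_complete = attr(led, "unique_complete"),
                          allelic_ratio_input = ai$input_mean,
                          allelic_ratio_chip = ai$chip_mean,
                          allelic_p = ai$p_value),
                     "results/prioritization_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
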