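# Shared fixtures, built in code at test time.

# C/EBP-like PFM whose consensus is the 9-bp TTTGTCAAC site; the 8th
# position is the variable adenine. Dominant count 85 vs 5 elsewhere gives
# a single-mismatch relative-score drop of ~11%.
cebp_like_pfm <- function() {
  cons <- "TTTGTCAAC"
  counts <- matrix(5, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (k in 1:9)
    counts[match(substr(cons, k, k), c("A", "C", "G", "T")), k] <- 85
  position_frequency_matrix("CEBPB_like", counts, "SYN0001")
}

# Sequence context with the TTTGTCAAC site; the variable adenine (motif
# position 8) sits at 0-based offset 16.
cebp_context <- function(allele = "A") {
  paste0("GATTACAGG", "TTTGTCA", allele, "C", "CGATTACAG")
}

# Minimal phased VCF text, three diploid samples, two sites.
write_toy_phased_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    paste(c("chr9", "101", "rs_t1", "A", "G", ".", "PASS", "AA=A", "GT",
            "0|0", "0|1", "1|1"), collapse = "\t"),
    paste(c("chr9", "202", "rs_t2", "C", "T", ".", "PASS", "AA=T", "GT",
            "0|1", "0|0", "1|0"), collapse = "\t")), path)
  path
}

# VCF with n_sites biallelic SNPs plus `multi` multi-allelic records and one
# rare site (single alt allele among the samples).
write_filter_vcf <- function(path, n_samples = 50, n_sites = 17, multi = 3) {
  set.seed(42)
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("s", seq_len(n_samples))),
                 collapse = "\t"))
  rows <- character(0)
  gt_common <- function() paste0(rbinom(n_samples, 1, 0.4), "/",
                                 rbinom(n_samples, 1, 0.4))
  for (i in seq_len(n_sites)) {
    gts <- if (i == 1) c("0/1", rep("0/0", n_samples - 1)) else gt_common()
    rows <- c(rows, paste(c("chr9", 1000 + i * 10, paste0("rs_f", i), "A",
                            "G", ".", "PASS", ".", "GT", gts),
                          collapse = "\t"))
  }
  for (i in seq_len(multi)) {
    rows <- c(rows, paste(c("chr9", 5000 + i * 10, paste0("rs_m", i), "A",
                            "G,T", ".", "PASS", ".", "GT",
                            rep("0/1", n_samples)), collapse = "\t"))
  }
  writeLines(c(hdr, rows), path)
  path
}

# Tiny MAF file: two species, the reference row carrying one gap.
write_gapped_maf <- function(path) {
  writeLines(c("##maf version=1",
               "a score=1.0",
               "s hgT.chr9 100 7 + 1000 ACG-TGA",
               "s spA.chrX 0 8 + 1000 ACGCTGA",
               ""), path)
  path
}

# JASPAR text with two matrices for one TF (different information content)
# and one for another TF.
write_jaspar_fixture <- function(path) {
  writeLines(c(
    ">SYN0001.1\tCEBPB_like",
    "A  [  5  5  5  5  5 85 85  5  5 ]",
    "C  [  5 85  5  5 85  5  5  5 85 ]",
    "G  [  5  5  5 85  5  5  5 85  5 ]",
    "T  [ 85  5 85  5  5  5  5  5  5 ]",
    ">SYN0001.2\tCEBPB_like",
    "A  [ 30 30 20 20 ]",
    "C  [ 30 20 30 20 ]",
    "G  [ 20 30 20 30 ]",
    "T  [ 20 20 30 30 ]",
    ">SYN0002.1\tOTHER_TF",
    "A  [ 90  0  0 ]",
    "C  [  0 90  0 ]",
    "G  [  0  0 90 ]",
    "T  [  0  0  0 ]"), path)
  path
}

# Haplotype fixture: explicit matrix + positions.
toy_haps <- function(rows, positions) {
  H <- do.call(rbind, lapply(rows, function(r)
    as.integer(strsplit(r, "")[[1]])))
  haplotype_set(H, positions, population = rep("POP1", nrow(H)))
}

# Random small haplotype fixture for oracle sweeps.
random_haps <- function(n, S, seed) {
  set.seed(seed)
  repeat {
    H <- matrix(rbinom(n * S, 1, runif(1, 0.2, 0.8)), n, S)
    cnt <- colSums(H)
    if (all(cnt > 0 & cnt < n)) break
  }
  haplotype_set(H, positions = sort(sample.int(10000, S)),
                population = rep("POP1", n))
}
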