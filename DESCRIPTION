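Package: fireqtl
Title: eQTL Mapping, Motif Conservation and Selection Scans at a Regulatory Variant
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for linking a single regulatory variant to the
    control of interferon-beta (IFNB1) expression in activated monocytes:
    cis- and trans-eQTL mapping on inverse-normal-transformed expression with
    permutation-based family-wise error calibration, position-weight-matrix
    scanning with cross-species transcription-factor-binding-site conservation
    and allele-impact scoring, population-genetic selection scans (Weir-Cockerham
    FST, Tajima's D, EHH/iHS with derived-allele-frequency bin standardization,
    chromosome-wide empirical p-values), and a multi-criterion variant
    prioritization report. Ships seeded synthetic-data generators (genotype and
    expression panels with planted cis effects, forward Wright-Fisher haplotype
    simulation with recombination and selective sweeps, ortholog alignment
    blocks with planted motifs) so every stage is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
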