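# End-to-end orchestration on a (typically synthetic) input bundle:
# cis scan -> permutation FWER -> conditional scan -> trans scan -> motif
# conservation -> selection scan -> prioritization, written as one JSON+TSV
# report bundle.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic annotation tracks for a prioritization test bundle
#'
#' Builds the three interval tracks and the per-base conservation scores so
#' that exactly one chosen variant satisfies the track-based criteria:
#' intervals are tight around the chosen variant (never reaching the
#' neighbouring SNPs) and its GERP score is above the conservation cutoff,
#' while a configurable number of decoy intervals and sub-threshold scores
#' are scattered over the other variants.
#'
#' @param geno a `GenotypeMatrix`.
#' @param causal_id variant id to be fully annotated.
#' @param seed RNG seed for the decoys.
#' @param n_decoys number of other variants receiving partial annotation
#'   (default 5).
#' @return list: `tracks` (named list of `AnnotationTrack`), `gerp`.
#' @export
synthetic_prioritization_tracks <- function(geno, causal_id, seed = 1,
                                            n_decoys = 5) {
  set.seed(seed)
  v <- geno$variants
  j <- match(causal_id, v$id)
  if (is.na(j)) stop("variant not found: ", causal_id)
  gap <- min(abs(v$pos[-j] - v$pos[j]))
  hw <- max(1L, min(100L, gap %/% 2L - 1L))
  tight <- function(pos) GenomicRanges::GRanges(
    v$chrom[1], IRanges::IRanges(start = pos - hw + 1L, width = 2L * hw))
  others <- sample(setdiff(seq_len(nrow(v)), j), min(n_decoys, nrow(v) - 1))
  tracks <- list(
    ortholog_region = annotation_track(tight(v$pos[j]), "ortholog_region"),
    ensembl_regulatory = annotation_track(
      tight(c(v$pos[j], v$pos[others])), "ensembl_regulatory"),
    encode_tfbs = annotation_track(
      tight(c(v$pos[j], v$pos[others])), "encode_tfbs"))
  gerp <- annotation_track(NULL, "gerp", scores = data.frame(
    chrom = v$chrom[1],
    pos = v$pos,
    score = ifelse(seq_len(nrow(v)) == j, 2.8, runif(nrow(v), -2, 1.8))))
  list(tracks = tracks, gerp = gerp)
}

#' Run the full analysis pipeline on a configured input bundle
#'
#' Executes, in order: synthetic-data generation (or use of supplied
#' objects), the cis-eQTL scan with permutation FWER calibration, the
#' conditional scan on the lead SNP, the trans scan, motif conservation and
#' allele impact at the lead variant, the selection scan, and the
#' five-criterion prioritization. Everything is seeded from `config$seed`,
#' so the same configuration reproduces a byte-identical report.
#'
#' A failing stage aborts with the stage name; outputs of completed stages
#' are already on disk. A missing PFM input downgrades the motif criteria to
#' "unknown" instead of failing.
#'
#' @param config list with entries `seed`, `out_dir`, and optionally
#'   `eqtl_spec`, `hap_spec`, `aln_spec` (generator specs; defaults are
#'   used where missing), `pfm` (a `PositionFrequencyMatrix` or JASPAR
#'   path, or `NULL` to skip motif analysis), `n_permutations` (default
#'   200), `target_fwer` (0.01), `trans_condition` (`"LPS"`), `fdr` (0.01),
#'   `min_abs_beta` (0.2), `ld_threshold` (0.5).
#' @return list of class `PipelineReport` (also written to
#'   `out_dir/report.json` plus TSV tables), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config must name a seed")
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  report <- list(seed = config$seed)
  on_error <- function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  tryCatch({
    stage <- "simulate"
    espec <- config$eqtl_spec %||% eqtl_sim_spec(seed = config$seed)
    sim <- simulate_eqtl_dataset(espec)
    hspec <- config$hap_spec %||% hap_sim_spec(seed = config$seed + 1)
    haps <- simulate_haplotypes(hspec)
    # default alignment: focal column on the variable adenine (8th base)
    # of the C/EBP-like TTTGTCAAC consensus, as at the motivating variant
    aspec <- config$aln_spec %||% aln_sim_spec(motif_offset = -7,
                                               seed = config$seed + 2)
    aln <- simulate_ortholog_alignment(aspec)
    report$truth <- sim$truth

    stage <- "eqtl_cis"
    cis <- map_cis_eqtl(sim$genotypes, sim$expression,
                        sim$truth$target_gene)
    cal <- permutation_fwer_threshold(
      sim$genotypes, sim$expression, sim$truth$target_gene,
      n_permutations = config$n_permutations %||% 200,
      target_fwer = config$target_fwer %||% 0.01,
      seed = config$seed + 3)
    lead <- cis$snp[which.min(cis$p)]
    cis$significant <- cis$p < cal$threshold
    utils::write.table(cis, file.path(config$out_dir, "cis_eqtl.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cond <- conditional_scan(sim$genotypes, sim$expression,
                             sim$truth$target_gene, condition_on = lead)
    report$cis <- list(lead_snp = lead,
                       lead_p = min(cis$p),
                       fwer_threshold = cal$threshold,
                       n_significant = sum(cis$significant),
                       n_significant_conditional =
                         sum(cond$p < cal$threshold))

    stage <- "eqtl_trans"
    trans <- map_trans_eqtl(sim$genotypes, lead, sim$expression,
                            condition = config$trans_condition %||% "LPS",
                            fdr = config$fdr %||% 0.01,
                            min_abs_beta = config$min_abs_beta %||% 0.2)
    utils::write.table(trans$all, file.path(config$out_dir,
                                            "trans_eqtl.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$trans <- list(n_genes_tested = nrow(trans$all),
                         n_hits = nrow(trans$hits),
                         frac_down = if (nrow(trans$hits))
                           mean(trans$hits$direction == "down") else NA)

    stage <- "motif"
    pfm <- config$pfm
    if (is.character(pfm)) pfm <- read_jaspar_pfm(pfm)[[1]]
    calls <- NULL
    if (!is.null(pfm)) {
      pwm <- pfm_to_pwm(pfm)
      focal_pos <- aln$ref_start + aln$focal_column - 1L
      call <- cross_species_conservation(pwm, aln, focal_pos)
      human <- gsub("-", "", aln$rows[[aln$ref_species]])
      imp <- allele_impact(pwm, human, focal_pos - aln$ref_start, "A", "G")
      calls <- setNames(list(list(call)), lead)
      report$motif <- list(tf = pwm$tf_name,
                           n_species_detected = call$n_species_detected,
                           conserved = call$conserved,
                           delta_fraction = imp$delta_fraction,
                           decreased = imp$decreased)
    } else {
      report$motif <- list(skipped = "no PFM input; criteria unknown")
    }

    stage <- "selection"
    taj <- tajimas_d(haps)
    fst <- fst_amova(sim$genotypes)
    focal_fst <- fst$per_site$fst[match(lead, fst$per_site$id)]
    emp <- empirical_pvalue(focal_fst,
                            fst$per_site$fst[fst$per_site$id != lead])
    report$selection <- list(tajima_d = taj$D,
                             global_fst = fst$global,
                             lead_fst = focal_fst,
                             lead_fst_p_emp = emp$p_emp)

    stage <- "prioritize"
    ann <- config$annotations %||%
      synthetic_prioritization_tracks(sim$genotypes, lead,
                                      seed = config$seed + 4)
    dos <- impute_dosages(sim$genotypes)
    ld <- apply(dos, 1, function(row)
      suppressWarnings(ld_r2(row, dos[match(lead, rownames(dos)), ])))
    best_p <- tapply(cis$p, cis$snp, min)
    cand <- data.frame(id = sim$genotypes$variants$id,
                       chrom = sim$genotypes$variants$chrom,
                       pos = sim$genotypes$variants$pos,
                       eqtl_p = as.numeric(
                         best_p[sim$genotypes$variants$id]),
                       ld_r2 = ld)
    cand <- cand[!is.na(cand$ld_r2), ]
    led <- prioritize_variants(cand, tracks = ann$tracks, gerp = ann$gerp,
                               conservation_calls = calls,
                               ld_threshold = config$ld_threshold %||% 0.5)
    utils::write.table(as.data.frame(led),
                       file.path(config$out_dir, "prioritization.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$prioritization <- list(top_variant = led$id[1],
                                  n_candidates = nrow(led),
                                  top_n_criteria = led$n_criteria[1],
                                  unique_complete =
                                    attr(led, "unique_complete"))
  }, error = on_error)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(report, class = "PipelineReport"))
}
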