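# Five-criterion regulatory-variant prioritization and allelic-imbalance
# quantification for ChIP validation data.

#' Prioritize candidate variants against regulatory evidence
#'
#' Each candidate in the LD block (`ld_r2 >= ld_threshold` with the lead
#' variant) is scored on five boolean criteria:
#'
#' 1. `c1_ortholog_enhancer` - lies in a region orthologous to a validated
#'    enhancer (track with source `ortholog_region`);
#' 2. `c2_regulatory_element` - overlaps a predicted regulatory element
#'    (`ensembl_regulatory` track);
#' 3. `c3_encode_tfbs` - overlaps an experimentally defined TF binding site
#'    (`encode_tfbs` track);
#' 4. `c4_gerp_conserved` - per-base GERP rejected-substitutions score > 2 at
#'    the site;
#' 5. `c5_conserved_tfbs` - overlaps at least one cross-species conserved TF
#'    binding site (a `ConservationCall` with `conserved = TRUE`).
#'
#' A missing track makes its criterion `NA` ("unknown") and excludes it from
#' the count, so partially annotated runs stay comparable. Candidates are
#' ranked by the number of satisfied criteria (descending), ties broken by
#' eQTL p-value (ascending).
#'
#' @param candidates data.frame with columns `id`, `chrom`, `pos` (0-based),
#'   `eqtl_p`, and optionally `ld_r2` (r-squared with the lead variant;
#'   absent means keep all).
#' @param tracks named list of `AnnotationTrack`s; recognized names:
#'   `ortholog_region`, `ensembl_regulatory`, `encode_tfbs`. Missing entries
#'   give unknown criteria.
#' @param gerp an `AnnotationTrack` with per-base scores, or `NULL`.
#' @param conservation_calls named list (variant id -> list of
#'   `ConservationCall`s at that variant), or `NULL`.
#' @param ld_threshold LD r-squared defining the candidate block
#'   (default 0.5).
#' @param gerp_threshold conservation cutoff on the score (default 2,
#'   strictly greater).
#' @return data.frame of class `CriteriaLedger`, ranked, with the five
#'   criteria, `n_criteria`, `n_known`, and an attribute
#'   `"unique_complete"`: TRUE iff exactly one variant satisfies all five.
#' @export
prioritize_variants <- function(candidates, tracks = list(), gerp = NULL,
                                conservation_calls = NULL, ld_threshold = 0.5,
                                gerp_threshold = 2) {
  stopifnot(nrow(candidates) > 0,
            all(c("id", "chrom", "pos", "eqtl_p") %in% names(candidates)))
  if (!is.null(candidates$ld_r2))
    candidates <- candidates[candidates$ld_r2 >= ld_threshold, , drop = FALSE]
  if (nrow(candidates) == 0) stop("no candidates within the LD block")
  led <- candidates
  crit_track <- function(name) {
    tr <- tracks[[name]]
    if (is.null(tr)) return(rep(NA, nrow(led)))
    track_overlaps(tr, led$chrom, led$pos)
  }
  led$c1_ortholog_enhancer <- crit_track("ortholog_region")
  led$c2_regulatory_element <- crit_track("ensembl_regulatory")
  led$c3_encode_tfbs <- crit_track("encode_tfbs")
  led$c4_gerp_conserved <- if (is.null(gerp)) NA else {
    s <- track_score_at(gerp, led$chrom, led$pos)
    !is.na(s) & s > gerp_threshold
  }
  led$c5_conserved_tfbs <- if (is.null(conservation_calls)) NA else
    vapply(led$id, function(v) {
      calls <- conservation_calls[[v]]
      !is.null(calls) && any(vapply(calls, `[[`, TRUE, "conserved"))
    }, TRUE)
  crit <- as.matrix(led[, c("c1_ortholog_enhancer", "c2_regulatory_element",
                            "c3_encode_tfbs", "c4_gerp_conserved",
                            "c5_conserved_tfbs")])
  led$n_criteria <- rowSums(crit, na.rm = TRUE)
  led$n_known <- rowSums(!is.na(crit))
  led <- led[order(-led$n_criteria, led$eqtl_p), ]
  rownames(led) <- NULL
  complete <- led$n_known == 5 & led$n_criteria == 5
  attr(led, "unique_complete") <- sum(complete) == 1
  class(led) <- c("CriteriaLedger", "data.frame")
  led
}

#' @export
print.CriteriaLedger <- function(x, ...) {
  cat("CriteriaLedger:", nrow(x), "candidates; top:", x$id[1],
      sprintf("(%d/%d criteria)\n", x$n_criteria[1], x$n_known[1]))
  if (isTRUE(attr(x, "unique_complete")))
    cat("  exactly one variant satisfies all five criteria\n")
  NextMethod()
}

#' Allelic imbalance of ChIP versus input signal
#'
#' For heterozygous donors, computes the per-donor allelic ratio (allele-A
#' over allele-B signal) in the input and after immunoprecipitation, and the
#' per-donor enrichment `chip_ratio / input_ratio`. The paired comparison of
#' chip versus input ratios is performed on the log scale (two-sided paired
#' t-test; Wilcoxon signed-rank for fewer than 6 donors, where normality is
#' uncheckable); the group summary is mean and s.e.m. of the ratios on the
#' natural scale.
#'
#' @param donors data.frame with columns `input_a`, `input_b`, `chip_a`,
#'   `chip_b` (one row per donor; all signals must be positive - others are
#'   excluded with a warning).
#' @return list of class `AllelicRatioResult`: `per_donor` (ratios and
#'   enrichment), `input_mean`, `input_sem`, `chip_mean`, `chip_sem`,
#'   `p_value`, `test`, `n`.
#' @export
allelic_imbalance <- function(donors) {
  need <- c("input_a", "input_b", "chip_a", "chip_b")
  stopifnot(all(need %in% names(donors)))
  ok <- rowSums(as.matrix(donors[, need]) <= 0 |
                  is.na(as.matrix(donors[, need]))) == 0
  if (any(!ok))
    warning(sum(!ok), " donor(s) with non-positive signal excluded")
  donors <- donors[ok, , drop = FALSE]
  n <- nrow(donors)
  if (n < 3) stop("need at least 3 usable donors")
  per <- data.frame(input_ratio = donors$input_a / donors$input_b,
                    chip_ratio = donors$chip_a / donors$chip_b)
  per$enrichment <- per$chip_ratio / per$input_ratio
  sem <- function(x) sd(x) / sqrt(length(x))
  if (all(per$chip_ratio == per$input_ratio)) {
    p <- 1
    test <- "identical ratios"
  } else if (n >= 6) {
    p <- t.test(log(per$chip_ratio), log(per$input_ratio),
                paired = TRUE)$p.value
    test <- "paired t on log ratios"
  } else {
    p <- wilcox.test(log(per$chip_ratio), log(per$input_ratio),
                     paired = TRUE, exact = TRUE)$p.value
    test <- "Wilcoxon signed rank"
  }
  structure(list(per_donor = per, n = n,
                 input_mean = mean(per$input_ratio),
                 input_sem = sem(per$input_ratio),
                 chip_mean = mean(per$chip_ratio),
                 chip_sem = sem(per$chip_ratio),
                 p_value = p, test = test),
            class = "AllelicRatioResult")
}

#' @export
print.AllelicRatioResult <- function(x, ...) {
  cat(sprintf("Allelic ratio: input %.2f +/- %.2f, ChIP %.2f +/- %.2f (n=%d, p=%.3g, %s)\n",
              x$input_mean, x$input_sem, x$chip_mean, x$chip_sem, x$n,
              x$p_value, x$test))
  invisible(x)
}
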