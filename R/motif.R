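# PFM -> PWM conversion, window scanning with min-max relative scores,
# cross-species conservation calling on alignment blocks, allele-impact
# scoring at a focal variant, and the expression filter on impacted TFs.

.BASES <- c("A", "C", "G", "T")

# Encode a sequence string as integers 1..4 (NA for N/gaps/others).
.seq_to_int <- function(s) {
  chars <- if (length(s) == 1L && is.character(s)) strsplit(s, "")[[1]] else s
  match(toupper(chars), .BASES)
}

.revcomp_int <- function(v) rev(5L - v)

#' Convert a position frequency matrix to a position weight matrix
#'
#' Log probability ratio method: per cell
#' `p = (count + pseudocount * background) / (column_total + pseudocount)`,
#' `weight = log2(p / background)`, with a uniform background of 0.25 per
#' nucleotide and a default pseudocount of 0.8 distributed by background.
#' The best and worst attainable raw scores are stored for min-max relative
#' scoring.
#'
#' @param pfm a `PositionFrequencyMatrix`.
#' @param pseudocount pseudocount added to each column total (default 0.8);
#'   must be > 0 when any count is zero, otherwise weights diverge.
#' @return object of class `PositionWeightMatrix` with fields `weights`
#'   (4 x L log2-odds), `max_score`, `min_score`.
#' @export
pfm_to_pwm <- function(pfm, pseudocount = 0.8) {
  counts <- pfm$counts
  if (any(counts < 0)) stop("negative counts in PFM")
  if (pseudocount <= 0 && any(counts == 0))
    stop("zero counts give -Inf weights; use a pseudocount > 0")
  bg <- 0.25
  tot <- colSums(counts)
  p <- sweep(counts + pseudocount * bg, 2, tot + pseudocount, "/")
  w <- log2(p / bg)
  structure(list(tf_name = pfm$tf_name, matrix_id = pfm$matrix_id,
                 weights = w, length = ncol(w),
                 pseudocount = pseudocount, background = bg,
                 max_score = sum(apply(w, 2, max)),
                 min_score = sum(apply(w, 2, min))),
            class = "PositionWeightMatrix")
}

#' @export
print.PositionWeightMatrix <- function(x, ...) {
  cat(sprintf("PositionWeightMatrix %s: L=%d, raw score range [%.3f, %.3f]\n",
              x$tf_name, x$length, x$min_score, x$max_score))
  invisible(x)
}

# Raw PWM scores at every start position of an integer-coded sequence.
# Windows containing NA (N or gap) score NA.
.pwm_raw_scores <- function(weights, seqint) {
  L <- ncol(weights)
  m <- length(seqint) - L + 1L
  if (m < 1L) return(numeric(0))
  s <- numeric(m)
  for (k in seq_len(L)) {
    b <- seqint[k:(k + m - 1L)]
    s <- s + weights[, k][b]
  }
  s
}

#' Scan a sequence window with a PWM
#'
#' Scores every start position on the forward strand and (by default) the
#' reverse complement, converts raw scores to min-max relative scores
#' `(raw - min) / (max - min)`, and retains hits with relative score at or
#' above `min_rel_score` that overlap the focal offset
#' (`start <= focal < start + L`). Windows containing `N` or gap characters
#' yield no hit.
#'
#' With `literal_max = TRUE` the threshold is instead applied to
#' `raw >= min_rel_score * max_score` (the literal "fraction of the maximum
#' score" reading); the default min-max convention matches the usual motif
#' scanning tools.
#'
#' @param pwm a `PositionWeightMatrix`.
#' @param sequence character string (or integer-coded vector) to scan.
#' @param focal_offset 0-based offset of the focal position in `sequence`,
#'   or `NULL` to keep all hits regardless of overlap.
#' @param both_strands scan the reverse strand too (default TRUE).
#' @param min_rel_score relative-score threshold (default 0.85); `0` keeps
#'   every scored window.
#' @param literal_max use the literal fraction-of-max threshold instead of
#'   min-max scaling.
#' @return data.frame of hits: `tf_name`, `start` (0-based), `strand`,
#'   `raw_score`, `relative_score`, `overlaps_focal`.
#' @export
scan_window <- function(pwm, sequence, focal_offset = NULL,
                        both_strands = TRUE, min_rel_score = 0.85,
                        literal_max = FALSE) {
  v <- if (is.character(sequence)) .seq_to_int(sequence) else sequence
  L <- pwm$length
  empty <- data.frame(tf_name = character(), start = integer(),
                      strand = character(), raw_score = numeric(),
                      relative_score = numeric(), overlaps_focal = logical())
  if (length(v) < L) return(empty)
  if (!is.null(focal_offset) &&
      (focal_offset < 0 || focal_offset >= length(v)))
    stop("focal_offset outside the sequence")
  fwd <- .pwm_raw_scores(pwm$weights, v)
  rng <- pwm$max_score - pwm$min_score
  rel <- function(raw) (raw - pwm$min_score) / rng
  starts <- seq_along(fwd) - 1L
  res <- data.frame(tf_name = pwm$tf_name, start = starts, strand = "+",
                    raw_score = fwd, relative_score = rel(fwd))
  if (both_strands) {
    # scoring the reverse complement of each window in place
    rcw <- pwm$weights[4:1, L:1, drop = FALSE]
    rev_scores <- .pwm_raw_scores(rcw, v)
    res <- rbind(res, data.frame(tf_name = pwm$tf_name, start = starts,
                                 strand = "-", raw_score = rev_scores,
                                 relative_score = rel(rev_scores)))
  }
  res <- res[!is.na(res$raw_score), , drop = FALSE]
  keep <- if (literal_max) res$raw_score >= min_rel_score * pwm$max_score
          else res$relative_score >= min_rel_score
  res <- res[keep, , drop = FALSE]
  res$overlaps_focal <- if (is.null(focal_offset)) NA else
    res$start <= focal_offset & focal_offset < res$start + L
  if (!is.null(focal_offset))
    res <- res[res$overlaps_focal, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cross-species conservation of a motif at a focal position
#'
#' For each species aligned in a window of `window` bp centred on the focal
#' reference position, the species' row is degapped and rescanned with
#' [scan_window()]; a species counts as carrying the site if at least one
#' hit overlaps the (mapped) focal position. The site is called conserved
#' when strictly more than `species_threshold` species carry it.
#'
#' If the focal column is a gap in a species, the nearest aligned flanking
#' position of that species is used as its focal position (permissive
#' overlap; such species are flagged in the per-species table).
#'
#' @param pwm a `PositionWeightMatrix`.
#' @param block an `AlignmentBlock`.
#' @param focal_ref_pos 0-based reference position of the variant.
#' @param window window width in bp (default 21, i.e. focal +/- 10).
#' @param species_threshold conservation calls require
#'   `n_species_detected > species_threshold` (default 20).
#' @param min_rel_score relative-score threshold passed to [scan_window()].
#' @return list of class `ConservationCall`: `tf_name`,
#'   `n_species_detected`, `conserved`, `species_threshold`, and `per_species`
#'   (best overlapping hit per species).
#' @export
cross_species_conservation <- function(pwm, block, focal_ref_pos,
                                       window = 21, species_threshold = 20,
                                       min_rel_score = 0.85) {
  fc <- ref_to_column(block, focal_ref_pos)
  if (is.na(fc)) stop("focal position not covered by the alignment block")
  half <- (window - 1) %/% 2
  lo <- ref_to_column(block, max(block$ref_start, focal_ref_pos - half))
  hi <- ref_to_column(block, min(block$ref_start + length(block$column_of) - 1,
                                 focal_ref_pos + half))
  cols <- lo:hi
  per <- lapply(block$species, function(sp) {
    chars <- strsplit(block$rows[[sp]], "")[[1]][cols]
    aligned <- !chars %in% c(".", "-")
    if (!any(aligned)) return(NULL)
    sub <- chars[aligned]
    focal_rel <- which(cols == fc)
    n_before <- sum(aligned[seq_len(focal_rel - 1)])
    gap_at_focal <- !aligned[focal_rel]
    off <- if (gap_at_focal) max(0L, min(n_before, length(sub) - 1L))
           else n_before  # 0-based offset of the focal base after degapping
    hits <- scan_window(pwm, paste(sub, collapse = ""), focal_offset = off,
                        min_rel_score = min_rel_score)
    if (nrow(hits) == 0) return(NULL)
    best <- hits[which.max(hits$relative_score), ]
    best$species <- sp
    best$gap_at_focal <- gap_at_focal
    best
  })
  per <- do.call(rbind, per)
  n_det <- if (is.null(per)) 0L else nrow(per)
  structure(list(tf_name = pwm$tf_name, n_species_detected = n_det,
                 conserved = n_det > species_threshold,
                 species_threshold = species_threshold,
                 per_species = per),
            class = "ConservationCall")
}

#' @export
print.ConservationCall <- function(x, ...) {
  cat(sprintf("ConservationCall %s: detected in %d species -> %s (threshold >%d)\n",
              x$tf_name, x$n_species_detected,
              if (x$conserved) "conserved" else "not conserved",
              x$species_threshold))
  invisible(x)
}

#' Classify an allele-impact score pair
#'
#' @param score_ancestral,score_derived best overlapping relative scores for
#'   the two alleles.
#' @param decrease_threshold fractional score decrease above which the TF is
#'   flagged (strictly greater; default 0.10).
#' @return list: `delta_fraction = (anc - der) / anc` and `decreased`.
#' @export
impact_call <- function(score_ancestral, score_derived,
                        decrease_threshold = 0.10) {
  delta <- if (score_ancestral == 0) NA_real_
           else (score_ancestral - score_derived) / score_ancestral
  list(delta_fraction = delta,
       decreased = !is.na(delta) && delta > decrease_threshold)
}

#' Impact of an allele substitution on predicted TF binding
#'
#' Substitutes each allele at the focal offset of the (human) sequence
#' window, and takes the best relative score over all windows overlapping the
#' focal position and both strands - regardless of the scanning threshold, so
#' the score difference is always defined. The binding is called decreased
#' when the relative score drops by more than `decrease_threshold`
#' (fractionally, relative to the ancestral score).
#'
#' @param pwm a `PositionWeightMatrix`.
#' @param sequence_window character string around the variant.
#' @param focal_offset 0-based offset of the variant within the window.
#' @param ancestral_base,derived_base the two alleles (A/C/G/T, different).
#' @param decrease_threshold see [impact_call()].
#' @return list of class `AlleleImpact`: `tf_name`, `score_ancestral`,
#'   `score_derived`, `delta_fraction`, `decreased`.
#' @export
allele_impact <- function(pwm, sequence_window, focal_offset,
                          ancestral_base, derived_base,
                          decrease_threshold = 0.10) {
  if (!all(c(ancestral_base, derived_base) %in% .BASES))
    stop("alleles must be A, C, G or T")
  v <- .seq_to_int(sequence_window)
  if (focal_offset < 0 || focal_offset >= length(v))
    stop("focal_offset outside the window")
  best_rel <- function(base) {
    w <- v
    w[focal_offset + 1L] <- match(base, .BASES)
    hits <- scan_window(pwm, w, focal_offset = focal_offset,
                        min_rel_score = 0)
    if (nrow(hits) == 0) return(0)
    max(hits$relative_score)
  }
  s_anc <- best_rel(ancestral_base)
  s_der <- best_rel(derived_base)
  cl <- impact_call(s_anc, s_der, decrease_threshold)
  structure(list(tf_name = pwm$tf_name, score_ancestral = s_anc,
                 score_derived = s_der,
                 delta_fraction = cl$delta_fraction,
                 decreased = cl$decreased),
            class = "AlleleImpact")
}

#' Filter allele impacts by TF expression
#'
#' Keeps the impacts whose transcription factor gene has mean raw FPKM at or
#' above `min_fpkm` in the stated condition, ranked by that expression. TFs
#' without a mapped gene are excluded with a warning.
#'
#' @param impacts list of `AlleleImpact` (or a data.frame with a `tf_name`
#'   column).
#' @param expr an `ExpressionMatrix` carrying raw FPKM (`fpkm_raw`).
#' @param min_fpkm expression cutoff (e.g. 1 for "expressed", 100 for
#'   "highly expressed").
#' @param tf2gene named character vector mapping TF name -> gene id.
#' @param condition condition whose samples are averaged (default `"LPS"`).
#' @return data.frame: `tf_name`, `gene`, `mean_fpkm`, `delta_fraction`,
#'   `decreased`, sorted by decreasing expression.
#' @export
expression_filter <- function(impacts, expr, min_fpkm, tf2gene,
                              condition = "LPS") {
  if (length(impacts) == 0)
    return(data.frame(tf_name = character(), gene = character(),
                      mean_fpkm = numeric(), delta_fraction = numeric(),
                      decreased = logical()))
  if (is.data.frame(impacts)) {
    tab <- impacts
  } else {
    tab <- do.call(rbind, lapply(impacts, function(im)
      data.frame(tf_name = im$tf_name, delta_fraction = im$delta_fraction,
                 decreased = im$decreased)))
  }
  if (is.null(expr$fpkm_raw)) stop("expression matrix lacks raw FPKM")
  gene <- tf2gene[tab$tf_name]
  unmapped <- is.na(gene)
  if (any(unmapped))
    warning("no gene mapping for TF(s): ",
            paste(tab$tf_name[unmapped], collapse = ", "))
  cols <- expr$condition == condition
  fpkm <- rowMeans(expr$fpkm_raw[, cols, drop = FALSE])
  names(fpkm) <- expr$genes
  tab$gene <- gene
  tab$mean_fpkm <- fpkm[gene]
  tab <- tab[!unmapped & !is.na(tab$mean_fpkm) & tab$mean_fpkm >= min_fpkm, ]
  tab <- tab[order(-tab$mean_fpkm), ]
  rownames(tab) <- NULL
  tab[, c("tf_name", "gene", "mean_fpkm", "delta_fraction", "decreased")]
}
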