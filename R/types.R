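# Shared S3 containers for the pipeline. Coordinates are 0-based half-open
# everywhere inside the package; VCF/MAF 1-based coordinates are converted at
# the I/O boundary.

#' Variant table constructor
#'
#' Builds the per-variant annotation table used inside [genotype_matrix()] and
#' [haplotype_set()]. Positions are 0-based; 1-based VCF positions must be
#' converted (`pos_vcf - 1`) before calling.
#'
#' @param chrom chromosome names.
#' @param pos 0-based reference positions.
#' @param id variant identifiers (e.g. `"rs12553564"`).
#' @param ref,alt single-nucleotide reference/alternate alleles.
#' @param ancestral ancestral allele, one of `ref`/`alt`, or `NA` when unknown.
#' @return a `data.frame` with class `variant_table`.
#' @export
variant_table <- function(chrom, pos, id, ref, alt, ancestral = NA_character_) {
  n <- length(pos)
  ancestral <- rep_len(as.character(ancestral), n)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  stopifnot(length(chrom) %in% c(1L, n), length(id) == n)
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases))
    stop("variant alleles must be single nucleotides in {A,C,G,T}")
  if (any(ref == alt))
    stop("ref and alt alleles must differ")
  bad_aa <- !is.na(ancestral) & ancestral != ref & ancestral != alt
  if (any(bad_aa))
    stop("ancestral allele matches neither ref nor alt for: ",
         paste(id[bad_aa], collapse = ", "))
  out <- data.frame(chrom = rep_len(as.character(chrom), n),
                    pos = as.integer(pos), id = id,
                    ref = ref, alt = alt, ancestral = ancestral,
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Genotype matrix container
#'
#' Dosage-coded genotypes (variants x individuals, values 0/1/2 or `NA`) with
#' per-individual population labels. Minor allele frequencies per population
#' and overall are computed from the dosages.
#'
#' @param variants a [variant_table()].
#' @param dosages integer matrix, variants x individuals, entries in
#'   `{0,1,2,NA}`. Missing genotypes are excluded pairwise from allele
#'   frequencies and mean-imputed for regression (see [impute_dosages()]).
#' @param individuals sample identifiers (columns of `dosages`).
#' @param population per-individual population label (e.g. `"AFB"`/`"EUB"`).
#' @return an object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(variants, dosages, individuals, population) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == nrow(variants),
            ncol(dosages) == length(individuals),
            length(population) == length(individuals))
  if (!all(dosages %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  if (any(!nzchar(population)) || anyNA(population))
    stop("population labels must be non-empty")
  dimnames(dosages) <- list(variants$id, individuals)
  obj <- structure(list(variants = variants,
                        dosages = dosages,
                        individuals = individuals,
                        population = population),
                   class = "GenotypeMatrix")
  obj$maf <- compute_maf(obj)
  obj
}

#' Minor allele frequencies of a GenotypeMatrix
#'
#' Recomputes per-variant minor allele frequency per population and overall
#' from the dosages, excluding missing genotypes pairwise.
#'
#' @param geno a `GenotypeMatrix`.
#' @return data.frame with one `maf_<pop>` column per population plus
#'   `maf_overall` (all frequencies folded to `[0, 0.5]`).
#' @export
compute_maf <- function(geno) {
  pops <- unique(geno$population)
  fold <- function(f) pmin(f, 1 - f)
  af <- function(cols) rowMeans(geno$dosages[, cols, drop = FALSE],
                                na.rm = TRUE) / 2
  out <- data.frame(row.names = geno$variants$id)
  for (p in pops) out[[paste0("maf_", p)]] <- fold(af(geno$population == p))
  out$maf_overall <- fold(af(rep(TRUE, length(geno$individuals))))
  out
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", nrow(x$dosages), "variants x",
      ncol(x$dosages), "individuals\n")
  cat("  populations:", paste(sprintf("%s (n=%d)", names(table(x$population)),
                                      table(x$population)), collapse = ", "), "\n")
  invisible(x)
}

#' Haplotype set container
#'
#' Phased binary haplotypes coded 0 = ancestral, 1 = derived, with strictly
#' increasing physical positions. Derived allele frequencies are the column
#' means.
#'
#' @param haplotypes 2n x S binary matrix (rows = haplotypes, columns = sites).
#' @param positions strictly increasing physical positions (bp, 0-based).
#' @param population per-haplotype population label.
#' @param site_id optional per-site identifiers.
#' @param chrom chromosome name (single string).
#' @return object of class `HaplotypeSet` with a `daf` vector.
#' @export
haplotype_set <- function(haplotypes, positions, population,
                          site_id = NULL, chrom = "chrSim") {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  stopifnot(ncol(haplotypes) == length(positions),
            nrow(haplotypes) == length(population))
  if (!all(haplotypes %in% c(0L, 1L)))
    stop("haplotype entries must be 0 (ancestral) or 1 (derived)")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (is.null(site_id)) site_id <- paste0("site_", seq_along(positions))
  colnames(haplotypes) <- site_id
  structure(list(haplotypes = haplotypes,
                 positions = as.numeric(positions),
                 population = population,
                 site_id = site_id,
                 chrom = chrom,
                 daf = unname(colMeans(haplotypes))),
            class = "HaplotypeSet")
}

#' @export
print.HaplotypeSet <- function(x, ...) {
  cat("HaplotypeSet:", nrow(x$haplotypes), "haplotypes x",
      ncol(x$haplotypes), "sites on", x$chrom, "\n")
  if (length(x$positions))
    cat("  span:", min(x$positions), "-", max(x$positions), "bp\n")
  invisible(x)
}

#' Expression matrix container
#'
#' log2 FPKM expression (genes x samples) with one condition and one
#' population label per sample, and the identifier of the individual each
#' sample was taken from (individuals appear once per condition).
#'
#' @param genes gene identifiers (rows).
#' @param values numeric matrix genes x samples of log2 FPKM.
#' @param condition per-sample stimulation condition
#'   (e.g. `"NS"`, `"LPS"`, `"PAM3"`, `"R848"`).
#' @param population per-sample population label.
#' @param individual per-sample individual identifier.
#' @param fpkm_raw optional untransformed FPKM matrix (same shape as `values`)
#'   used by expression filters.
#' @return object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(genes, values, condition, population, individual,
                              fpkm_raw = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(genes),
            ncol(values) == length(condition),
            length(population) == length(condition),
            length(individual) == length(condition))
  if (!all(is.finite(values))) stop("expression values must be finite")
  rownames(values) <- genes
  structure(list(genes = genes, values = values, condition = condition,
                 population = population, individual = individual,
                 fpkm_raw = fpkm_raw),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cat("  conditions:", paste(unique(x$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Alignment block container
#'
#' One stitched multiple-alignment block: per-species gapped rows over
#' `{A,C,G,T,N,-,.}` (`-` = gap within an aligned segment, `.` = species not
#' aligned at that column), anchored to a reference species whose ungapped
#' positions map to alignment columns.
#'
#' @param species ordered species names.
#' @param rows named character vector of equal-length gapped sequences.
#' @param ref_species name of the coordinate-bearing species.
#' @param ref_chrom reference chromosome name.
#' @param ref_start 0-based reference position of the first aligned reference
#'   base.
#' @return object of class `AlignmentBlock` with a `column_of` integer vector:
#'   `column_of[i]` is the 1-based alignment column of reference offset
#'   `i - 1`.
#' @export
alignment_block <- function(species, rows, ref_species,
                            ref_chrom = "chrSim", ref_start = 0L) {
  stopifnot(length(rows) == length(species), ref_species %in% species)
  names(rows) <- species
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("all alignment rows must have equal length")
  refchars <- strsplit(rows[[ref_species]], "")[[1]]
  column_of <- which(!refchars %in% c("-", "."))
  structure(list(species = species, rows = rows, ref_species = ref_species,
                 ref_chrom = ref_chrom, ref_start = as.integer(ref_start),
                 width = unname(widths[1]), column_of = column_of),
            class = "AlignmentBlock")
}

#' @export
print.AlignmentBlock <- function(x, ...) {
  cat("AlignmentBlock:", length(x$species), "species,", x$width, "columns;",
      "ref", x$ref_species, sprintf("%s:%d-%d", x$ref_chrom, x$ref_start,
                                    x$ref_start + length(x$column_of)), "\n")
  invisible(x)
}

#' Map a reference position to an alignment column
#'
#' @param block an `AlignmentBlock`.
#' @param ref_pos 0-based reference position(s).
#' @return 1-based alignment column indices (`NA` outside the block).
#' @export
ref_to_column <- function(block, ref_pos) {
  off <- ref_pos - block$ref_start
  ok <- off >= 0 & off < length(block$column_of)
  out <- rep(NA_integer_, length(off))
  out[ok] <- block$column_of[off[ok] + 1L]
  out
}

#' Position frequency matrix constructor
#'
#' @param tf_name transcription factor name.
#' @param counts 4 x L non-negative matrix, rows A, C, G, T.
#' @param matrix_id optional database identifier.
#' @return object of class `PositionFrequencyMatrix` with an
#'   `information_content` field (total IC in bits, base-2 logs, uniform
#'   background).
#' @export
position_frequency_matrix <- function(tf_name, counts, matrix_id = NA_character_) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("PFM must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) stop("PFM counts must be non-negative")
  if (any(colSums(counts) <= 0)) stop("PFM column sums must be positive")
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(tf_name = tf_name, matrix_id = matrix_id, counts = counts,
                 length = ncol(counts),
                 information_content = pfm_information_content(counts)),
            class = "PositionFrequencyMatrix")
}

#' Total information content of a PFM
#'
#' Per column `2 + sum(p * log2(p))` against a uniform background, summed over
#' columns; the per-TF matrix with the highest value is the one retained by
#' [read_jaspar_pfm()].
#'
#' @param counts 4 x L count matrix.
#' @return scalar information content in bits.
#' @export
pfm_information_content <- function(counts) {
  p <- sweep(counts, 2, colSums(counts), "/")
  plogp <- ifelse(p > 0, p * log2(p), 0)
  sum(2 + colSums(plogp))
}

#' @export
print.PositionFrequencyMatrix <- function(x, ...) {
  cat(sprintf("PositionFrequencyMatrix %s (%s): L=%d, IC=%.2f bits\n",
              x$tf_name, x$matrix_id, x$length, x$information_content))
  invisible(x)
}

#' Annotation track container
#'
#' Interval annotations (half-open, 0-based) kept as a `GRanges`, plus an
#' optional per-base score table (e.g. GERP rejected-substitution scores).
#'
#' @param intervals a `GRanges` (may be empty / `NULL` for score-only tracks).
#' @param source one of `"ensembl_regulatory"`, `"encode_tfbs"`,
#'   `"ortholog_region"` or a free label.
#' @param scores optional data.frame with columns `chrom`, `pos` (0-based) and
#'   `score`.
#' @return object of class `AnnotationTrack`.
#' @export
annotation_track <- function(intervals = NULL, source = "track", scores = NULL) {
  if (is.null(intervals)) intervals <- GenomicRanges::GRanges()
  structure(list(intervals = intervals, source = source, scores = scores),
            class = "AnnotationTrack")
}

#' Point-overlap query on an annotation track
#'
#' @param track an `AnnotationTrack`.
#' @param chrom chromosome name(s).
#' @param pos 0-based position(s).
#' @return logical vector: does any interval cover each position
#'   (half-open convention: an interval `[start, end)` covers `pos` iff
#'   `start <= pos < end`).
#' @export
track_overlaps <- function(track, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  if (length(track$intervals) == 0) return(rep(FALSE, n))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L,
                                                      width = 1L))
  # queries on chromosomes absent from the track are plain non-overlaps
  suppressWarnings(GenomicRanges::countOverlaps(q, track$intervals) > 0)
}

#' Per-base score lookup on an annotation track
#'
#' @param track an `AnnotationTrack` carrying a `scores` table.
#' @param chrom chromosome name(s).
#' @param pos 0-based position(s).
#' @return numeric score per position (`NA` where absent).
#' @export
track_score_at <- function(track, chrom, pos) {
  if (is.null(track$scores)) return(rep(NA_real_, length(pos)))
  key <- paste(rep_len(chrom, length(pos)), pos)
  track$scores$score[match(key, paste(track$scores$chrom, track$scores$pos))]
}

#' @export
print.AnnotationTrack <- function(x, ...) {
  cat("AnnotationTrack [", x$source, "]: ", length(x$intervals), " intervals",
      if (!is.null(x$scores)) paste0(", ", nrow(x$scores), " scored bases"),
      "\n", sep = "")
  invisible(x)
}
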