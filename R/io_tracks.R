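# BED interval tracks and per-base score tables (e.g. GERP rejected
# substitution scores), returned as AnnotationTrack objects backed by GRanges.

#' Read a BED3/BED4 file as an annotation track
#'
#' BED uses 0-based half-open intervals, which is also the internal
#' convention, so coordinates pass through unchanged. Intervals are sorted on
#' load; point queries go through [track_overlaps()].
#'
#' @param path BED file.
#' @param source track label (e.g. `"ensembl_regulatory"`, `"encode_tfbs"`,
#'   `"ortholog_region"`).
#' @return an [annotation_track()].
#' @export
read_bed <- function(path, source = "bed") {
  df <- utils::read.table(path, header = FALSE, sep = "", quote = "",
                          stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(df) < 3) stop("BED file needs at least 3 columns: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  bad <- df$start >= df$end
  if (any(bad))
    stop("BED line ", which(bad)[1], ": start >= end (",
         df$start[which(bad)[1]], " >= ", df$end[which(bad)[1]], ")")
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(start = df$start + 1L,
                                                end = df$end))
  if ("name" %in% names(df)) S4Vectors::mcols(gr)$name <- df$name
  annotation_track(GenomicRanges::sort(gr), source = source)
}

#' Read a two-column position/score table
#'
#' Tab-separated table of per-base conservation scores. Either three columns
#' (`chrom`, `pos`, `score`) or two (`pos`, `score`, with `chrom` supplied).
#' Positions in the file are 1-based and converted to 0-based internally.
#'
#' @param path TSV file.
#' @param chrom chromosome for two-column files.
#' @param source track label (default `"gerp"`).
#' @return an [annotation_track()] with a `scores` table; query with
#'   [track_score_at()].
#' @export
read_score_table <- function(path, chrom = NULL, source = "gerp") {
  df <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(df) == 2) {
    if (is.null(chrom)) stop("two-column score table needs a chrom argument")
    df <- data.frame(chrom = chrom, pos = df[[1]], score = df[[2]])
  } else {
    df <- data.frame(chrom = df[[1]], pos = df[[2]], score = df[[3]])
  }
  df$pos <- as.integer(df$pos) - 1L
  annotation_track(NULL, source = source, scores = df)
}

#' Write intervals as BED
#'
#' @param track an `AnnotationTrack` with intervals.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  gr <- track$intervals
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) df$name <- nm
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
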