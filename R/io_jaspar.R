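# JASPAR 2018 text-format position frequency matrices:
#   >MA0466.2  CEBPB
#   A  [  87 167 ... ]
#   C  [ ... ]  (rows may also omit the base letter and brackets)

#' Read JASPAR-format position frequency matrices
#'
#' Parses a JASPAR text file into [position_frequency_matrix()] objects. When
#' several matrices share a transcription-factor name, only the one with the
#' highest total information content is retained (the convention used for
#' motif scanning, where one matrix per TF is wanted).
#'
#' @param path JASPAR text file.
#' @param dedupe_by_ic keep only the highest-IC matrix per TF (default TRUE).
#' @return named list of `PositionFrequencyMatrix` (names = TF names).
#' @export
read_jaspar_pfm <- function(path, dedupe_by_ic = TRUE) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(list())
  heads <- which(grepl("^>", lines))
  if (length(heads) == 0) stop("no '>' headers in ", path)
  pfms <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    hdr <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1]]
    matrix_id <- hdr[1]
    tf_name <- if (length(hdr) >= 2) hdr[2] else hdr[1]
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4L)
      stop("matrix ", matrix_id, ": expected 4 count rows, got ", length(body))
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("matrix ", matrix_id, ": rows have unequal lengths (",
           paste(lens, collapse = ", "), ")")
    counts <- do.call(rbind, rows)
    pfms[[length(pfms) + 1L]] <-
      position_frequency_matrix(tf_name, counts, matrix_id)
  }
  if (dedupe_by_ic) {
    tf <- vapply(pfms, `[[`, "", "tf_name")
    ic <- vapply(pfms, `[[`, 0, "information_content")
    keep <- unlist(lapply(split(seq_along(pfms), tf),
                          function(ix) ix[which.max(ic[ix])]))
    pfms <- pfms[sort(keep)]
  }
  setNames(pfms, vapply(pfms, `[[`, "", "tf_name"))
}
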