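# Reader/writer for UCSC multiz-style MAF (Multiple Alignment Format) blocks.
# Blocks intersecting a reference interval are stitched in reference order;
# species missing from a block are marked unaligned ('.') over its columns.

#' Read a MAF multiple alignment restricted to a reference interval
#'
#' @param path MAF file path.
#' @param ref_species reference (coordinate-bearing) species prefix, as it
#'   appears before the dot in `s` lines (e.g. `"hg19"`).
#' @param ref_interval optional `list(chrom=, start=, end=)` (0-based
#'   half-open) on the reference; blocks not intersecting it are skipped.
#' @return an [alignment_block()] stitching all retained blocks, or `NULL`
#'   if none intersect.
#' @export
read_maf <- function(path, ref_species, ref_interval = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  starts <- which(grepl("^a", lines))
  if (length(starts) == 0) stop("no alignment blocks in ", path)
  bounds <- c(starts, length(lines) + 1L)
  blocks <- list()
  for (b in seq_along(starts)) {
    chunk <- lines[(bounds[b] + 1L):(bounds[b + 1L] - 1L)]
    slines <- chunk[grepl("^s\\s", chunk)]
    if (length(slines) == 0) next
    f <- lapply(strsplit(slines, "\\s+"), function(x) x)
    src <- vapply(f, `[`, "", 2)
    start <- as.integer(vapply(f, `[`, "", 3))
    txt <- toupper(vapply(f, function(x) x[length(x)], ""))
    sp <- sub("\\..*$", "", src)
    chromof <- sub("^[^.]*\\.", "", src)
    is_ref <- sp == ref_species
    if (!any(is_ref)) {
      warning("block ", b, " lacks reference species ", ref_species,
              "; skipped")
      next
    }
    r <- which(is_ref)[1]
    ref_len <- sum(strsplit(txt[r], "")[[1]] %in% c("A", "C", "G", "T", "N"))
    if (!is.null(ref_interval)) {
      if (chromof[r] != ref_interval$chrom ||
          start[r] >= ref_interval$end ||
          start[r] + ref_len <= ref_interval$start) next
    }
    blocks[[length(blocks) + 1L]] <-
      list(species = sp, rows = txt, ref_row = r,
           ref_chrom = chromof[r], ref_start = start[r], width = nchar(txt[1]))
  }
  if (length(blocks) == 0) return(NULL)
  ord <- order(vapply(blocks, `[[`, 0L, "ref_start"))
  blocks <- blocks[ord]
  all_sp <- unique(unlist(lapply(blocks, `[[`, "species")))
  ref_sp_first <- c(ref_species, setdiff(all_sp, ref_species))
  rows <- setNames(rep("", length(ref_sp_first)), ref_sp_first)
  for (blk in blocks) {
    pad <- strrep(".", blk$width)
    for (sp in ref_sp_first) {
      i <- match(sp, blk$species)
      rows[sp] <- paste0(rows[sp], if (is.na(i)) pad else blk$rows[i])
    }
  }
  alignment_block(species = ref_sp_first, rows = rows,
                  ref_species = ref_species,
                  ref_chrom = blocks[[1]]$ref_chrom,
                  ref_start = blocks[[1]]$ref_start)
}

#' Write an AlignmentBlock as a single MAF block
#'
#' @param block an `AlignmentBlock`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(block, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  writeLines("a score=0.0", con)
  for (sp in block$species) {
    row <- block$rows[[sp]]
    size <- sum(strsplit(row, "")[[1]] %in% c("A", "C", "G", "T", "N"))
    src <- if (sp == block$ref_species)
      paste0(sp, ".", block$ref_chrom) else paste0(sp, ".chrUn")
    start <- if (sp == block$ref_species) block$ref_start else 0L
    writeLines(sprintf("s %s %d %d + %d %s", src, start, size,
                       start + size, row), con)
  }
  writeLines("", con)
  invisible(path)
}
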