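# Expression matrix TSV: genes x samples of log2 FPKM with a three-line
# header (sample ids, condition labels, population labels, individual ids).

#' Read an expression matrix TSV
#'
#' Expects a tab-separated file whose first column is the gene id and whose
#' header rows give, in order: sample id, condition, population, individual.
#' The companion writer is [write_expression()].
#'
#' @param path TSV path.
#' @return an [expression_matrix()] (without raw FPKM).
#' @export
read_expression <- function(path) {
  lines <- readLines(path, n = 4)
  hdr <- strsplit(lines, "\t")
  if (!identical(vapply(hdr, `[`, "", 1),
                 c("sample", "condition", "population", "individual")))
    stop("expression TSV must start with sample/condition/population/individual header rows")
  samples <- hdr[[1]][-1]
  df <- data.table::fread(path, skip = 4, header = FALSE, data.table = FALSE)
  genes <- df[[1]]
  values <- as.matrix(df[, -1, drop = FALSE])
  colnames(values) <- samples
  expression_matrix(genes, values,
                    condition = hdr[[2]][-1],
                    population = hdr[[3]][-1],
                    individual = hdr[[4]][-1])
}

#' Write an expression matrix TSV
#'
#' @param expr an `ExpressionMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  samples <- colnames(expr$values)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(expr$values)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(c("sample", samples), collapse = "\t"),
               paste(c("condition", expr$condition), collapse = "\t"),
               paste(c("population", expr$population), collapse = "\t"),
               paste(c("individual", expr$individual), collapse = "\t")), con)
  utils::write.table(cbind(expr$genes, format(expr$values, trim = TRUE)),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Subset an ExpressionMatrix by sample
#'
#' @param expr an `ExpressionMatrix`.
#' @param which logical or integer index over samples.
#' @return the subsetted `ExpressionMatrix`.
#' @export
subset_samples <- function(expr, which) {
  expression_matrix(expr$genes, expr$values[, which, drop = FALSE],
                    expr$condition[which], expr$population[which],
                    expr$individual[which],
                    fpkm_raw = if (!is.null(expr$fpkm_raw))
                      expr$fpkm_raw[, which, drop = FALSE])
}
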