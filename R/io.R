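# Tidy delimited-text I/O. Tables are tab-separated with a header row;
# read.delim/write.table do the parsing, these wrappers only validate
# the expected columns.

#' Read / write tidy trace tables
#'
#' Trace tables hold one row per (cell, frame): `cell_id`, `time_s`, `F`,
#' `diameter_um` (may be `NA`).
#'
#' @param path File path (tab-separated, header row).
#' @return `read_trace_table()` returns the data frame;
#'   `write_trace_table()` returns `path` invisibly.
#' @export
read_trace_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_s", "F")
  if (!all(need %in% names(df)))
    ns_stop(sprintf("trace table must have columns %s",
                    paste(need, collapse = ", ")), "invalid-argument")
  df
}

#' @rdname read_trace_table
#' @param traces Tidy trace table.
#' @export
write_trace_table <- function(traces, path) {
  utils::write.table(traces, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read / write a gene-by-subtype expression matrix
#'
#' On disk: tab-separated, first column `gene`, remaining columns one per
#' subtype. Duplicate gene ids are rejected at load.
#'
#' @param path File path.
#' @return `read_expression_matrix()` returns a numeric matrix with gene
#'   rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (names(df)[1L] != "gene")
    ns_stop("first column of an expression matrix must be 'gene'",
            "invalid-argument")
  if (anyDuplicated(df$gene))
    ns_stop("duplicated gene ids", "invalid-argument")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_matrix
#' @param matrix Numeric matrix, gene rownames, subtype colnames.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a generic result table
#'
#' @param table Data frame.
#' @param path File path.
#' @export
write_result_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
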