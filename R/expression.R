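#' Expression call at a threshold
#'
#' A gene counts as expressed in a subtype when its expression summary
#' (normalised mean or fraction-of-cells, whichever the matrix carries)
#' is at or above the threshold (inclusive).
#'
#' @param value Nonnegative expression summary (vectorised).
#' @param on_threshold Nonnegative threshold.
#' @return Logical vector.
#' @export
is_expressed <- function(value, on_threshold) {
  check_number(on_threshold, "on_threshold", nonneg = TRUE)
  if (any(value < 0, na.rm = TRUE))
    ns_stop("expression values must be nonnegative", "invalid-argument")
  value >= on_threshold
}

#' Screen for GPCRs restricted to CGRP+ subtypes
#'
#' A gene is restricted when it is expressed (value >= `on_threshold`) in at
#' least one CGRP+ subtype and not expressed (value < `off_threshold`) in
#' every LTMR and proprioceptor subtype. Subtypes of class `"other"`
#' (e.g. TrpM8+ or MrgprD+ populations) neither qualify nor disqualify a
#' gene unless `strict_other = TRUE`, which adds them to the exclusion
#' classes. Using two thresholds keeps the asymmetric judgments
#' ("expressed in" vs "not expressed in") independent; with
#' `on_threshold == off_threshold` and a binary matrix the screen reduces
#' to exact set logic.
#'
#' @param matrix Numeric gene-by-subtype matrix, rownames = gene ids,
#'   colnames = subtype ids; values nonnegative, gene ids unique.
#' @param annotation Subtype annotation from [subtype_annotation()];
#'   must contain at least one CGRP and one LTMR subtype.
#' @param on_threshold Expression call threshold for CGRP+ subtypes
#'   (default 0.1, units of the input summary).
#' @param off_threshold Absence call threshold for exclusion classes
#'   (default = `on_threshold`; must be <= `on_threshold`).
#' @param strict_other Treat class `"other"` subtypes as exclusion classes.
#' @return A data frame of class `screen_result`, one row per gene:
#'   `gene`, `restricted`, `breadth` (number of CGRP+ subtypes expressing),
#'   `on_subtypes`, `off_violations` (comma-separated lists). Threshold
#'   metadata is attached as attributes `on_threshold`, `off_threshold`,
#'   `strict_other`.
#' @export
restriction_screen <- function(matrix, annotation, on_threshold = 0.1,
                               off_threshold = on_threshold,
                               strict_other = FALSE) {
  if (is.null(rownames(matrix)) || nrow(matrix) == 0L)
    ns_stop("gene universe is empty", "invalid-argument")
  if (anyDuplicated(rownames(matrix)))
    ns_stop("duplicated gene ids", "invalid-argument")
  if (any(matrix < 0))
    ns_stop("expression values must be nonnegative", "invalid-argument")
  check_number(on_threshold, "on_threshold", nonneg = TRUE)
  check_number(off_threshold, "off_threshold", nonneg = TRUE)
  if (off_threshold > on_threshold)
    ns_stop("off_threshold must be <= on_threshold", "invalid-argument")
  ann <- annotation[match(colnames(matrix), annotation$subtype_id), ]
  if (anyNA(ann$subtype_id))
    ns_stop("matrix has subtypes missing from the annotation",
            "invalid-argument")
  cgrp_cols <- which(ann$class == "CGRP")
  off_classes <- c("LTMR", "proprioceptor", if (strict_other) "other")
  off_cols <- which(ann$class %in% off_classes)
  if (length(cgrp_cols) == 0L ||
      !any(ann$class %in% c("LTMR", "proprioceptor")))
    ns_stop("annotation must contain >=1 CGRP and >=1 LTMR/proprioceptor subtype",
            "invalid-argument")

  on_mat <- matrix[, cgrp_cols, drop = FALSE] >= on_threshold
  viol_mat <- matrix[, off_cols, drop = FALSE] >= off_threshold
  breadth <- rowSums(on_mat)
  n_viol <- rowSums(viol_mat)
  cgrp_names <- colnames(matrix)[cgrp_cols]
  off_names <- colnames(matrix)[off_cols]
  out <- data.frame(
    gene = rownames(matrix),
    restricted = breadth >= 1L & n_viol == 0L,
    breadth = as.integer(breadth),
    on_subtypes = apply(on_mat, 1L, function(z)
      paste(cgrp_names[z], collapse = ",")),
    off_violations = apply(viol_mat, 1L, function(z)
      paste(off_names[z], collapse = ",")),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "on_threshold") <- on_threshold
  attr(out, "off_threshold") <- off_threshold
  attr(out, "strict_other") <- strict_other
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Breadth histogram over restricted genes
#'
#' Counts the restricted genes by the number of CGRP+ subtypes expressing
#' them, separating exclusively expressed genes (breadth 1) from broadly
#' expressed ones.
#'
#' @param results A [restriction_screen()] result.
#' @return A data frame (`breadth`, `n_genes`); counts sum to the number of
#'   restricted genes. Empty restricted set gives a zero-row frame.
#' @export
breadth_profile <- function(results) {
  r <- results[results$restricted, , drop = FALSE]
  if (nrow(r) == 0L)
    return(data.frame(breadth = integer(), n_genes = integer()))
  tab <- table(r$breadth)
  data.frame(breadth = as.integer(names(tab)),
             n_genes = as.integer(tab))
}
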