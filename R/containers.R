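# Domain containers. Kept deliberately light: expression data are numeric
# matrices (genes x samples) carrying a scale tag, labels are named character
# vectors, gene sets are named lists, clinical data are data frames. Each
# constructor validates the invariants the pipeline relies on.

#' Construct an expression matrix
#'
#' A genes x samples numeric matrix with unique gene and sample identifiers
#' and a declared expression scale. The scale is never sniffed from the
#' values: downstream operations state which scale they require and convert
#' (or refuse) explicitly.
#'
#' @param values Numeric matrix, genes as rows (rownames = gene symbols),
#'   samples as columns (colnames = sample identifiers).
#' @param scale `"linear"` (RPKM/TPM-like, non-negative) or `"log2"`
#'   (microarray-like).
#' @return A numeric matrix of class `"expr_matrix"` with a `scale` attribute.
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (nrow(values) == 0L || ncol(values) == 0L) stopf("expression matrix is empty")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("expression matrix needs gene rownames and sample colnames")
  }
  rownames(values) <- trimws(rownames(values))
  colnames(values) <- trimws(colnames(values))
  if (anyDuplicated(rownames(values))) {
    stopf("duplicate gene identifiers; collapse with collapse_duplicate_genes() first")
  }
  if (anyDuplicated(colnames(values))) stopf("duplicate sample identifiers")
  if (!all(is.finite(values))) stopf("expression values must be finite")
  if (scale == "linear" && any(values < 0)) {
    stopf("linear-scale expression values must be non-negative")
  }
  structure(values, scale = scale, class = c("expr_matrix", class(values)))
}

#' Expression scale of a matrix
#'
#' @param x An expression matrix.
#' @return `"linear"` or `"log2"`.
#' @export
expr_scale <- function(x) attr(x, "scale") %||% "linear"

#' Convert expression to linear scale
#'
#' Log2 matrices are exponentiated (`2^x`); linear matrices pass through.
#' Mixtures of cell populations are additive only in linear expression
#' units, so pseudo-bulk construction and deconvolution operate here.
#'
#' @param x An expression matrix.
#' @param warn Emit a warning when a conversion actually happens.
#' @return An `"expr_matrix"` on linear scale.
#' @export
to_linear <- function(x, warn = FALSE) {
  if (expr_scale(x) == "linear") return(x)
  if (warn) warnf("log2-scale input exponentiated to linear scale")
  expression_matrix(2 ^ unclass_expr(x), scale = "linear")
}

#' Convert expression to log2 scale
#'
#' @param x An expression matrix.
#' @param offset Pseudo-value added before taking logs of linear data.
#' @return An `"expr_matrix"` on log2 scale.
#' @export
to_log2 <- function(x, offset = 1) {
  if (expr_scale(x) == "log2") return(x)
  expression_matrix(log2(unclass_expr(x) + offset), scale = "log2")
}

unclass_expr <- function(x) {
  attr(x, "scale") <- NULL
  class(x) <- "matrix"
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

#' @export
#' @method print expr_matrix
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), expr_scale(x)))
  n <- min(5L, nrow(x)); m <- min(5L, ncol(x))
  print(unclass_expr(x)[seq_len(n), seq_len(m), drop = FALSE])
  if (nrow(x) > n || ncol(x) > m) cat("...\n")
  invisible(x)
}

#' Default cell-type vocabulary
#'
#' The nine flow-sorted hematopoietic populations of the HemLin9 signature:
#' AML blasts, common myeloid progenitors, granulocyte-monocyte progenitors,
#' hematopoietic stem cells, leukemic progenitor cells, leukemic stem cells,
#' megakaryocyte-erythrocyte progenitors, multipotent progenitors, and
#' Lin-CD34+CD38-CD90-CD45RA+ (RApos) cells.
#'
#' @return Character vector of the nine cell-type names.
#' @export
hemlin9_cell_types <- function() {
  c("AML_blast", "CMP", "GMP", "HSC", "LPC", "LSC", "MEP", "MPP", "RApos")
}

#' Construct sample-to-cell-type labels
#'
#' @param sample_id Character vector of sample identifiers.
#' @param cell_type Character vector, same length, of cell-type names.
#' @return Named character vector mapping sample id to cell type.
#' @export
cell_type_labels <- function(sample_id, cell_type) {
  sample_id <- trimws(as.character(sample_id))
  cell_type <- trimws(as.character(cell_type))
  if (length(sample_id) != length(cell_type)) stopf("id/type length mismatch")
  if (anyDuplicated(sample_id)) stopf("duplicate sample identifiers in labels")
  stats::setNames(cell_type, sample_id)
}

# Check labels against the matrix they annotate; every labeled sample must
# exist and every type needs >= min_reps replicates.
validate_labels <- function(labels, expr, min_reps = 2L) {
  missing <- setdiff(names(labels), colnames(expr))
  if (length(missing)) {
    stopf("labeled samples absent from expression matrix: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  tab <- table(labels)
  low <- names(tab)[tab < min_reps]
  if (length(low)) {
    stopf("cell type(s) with fewer than %d replicates: %s",
          min_reps, paste(low, collapse = ", "))
  }
  invisible(TRUE)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (gene symbols).
#' @param descriptions Optional character vector of per-set descriptions.
#' @return Named list of class `"gene_set_collection"`, genes deduplicated
#'   within each set, with a `descriptions` attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stopf("gene sets must have unique names")
  }
  sets <- lapply(sets, function(g) unique(trimws(as.character(g))))
  if (any(lengths(sets) == 0L)) stopf("gene sets must be non-empty")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "gene_set_collection")
}

#' @export
#' @method print gene_set_collection
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene set collection: %d sets\n", length(x)))
  for (nm in utils::head(names(x), 10L)) {
    cat(sprintf("  %s (%d genes)\n", nm, length(x[[nm]])))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Construct a survival table
#'
#' Per-sample time-to-event data with optional clinical covariates. The
#' cytogenetic-risk vocabulary is Favorable / Intermediate / Poor; cohort
#' spellings such as "FavorableOrIntermediate" are normalized by
#' [read_clinical_table()].
#'
#' @param sample_id Character sample identifiers (unique).
#' @param time Non-negative follow-up times (unit recorded in `time_unit`).
#' @param event 0/1 event indicator (1 = death observed).
#' @param ... Optional covariate columns (e.g. `age`, `sex`,
#'   `cytogenetic_risk`), each of the same length.
#' @param time_unit Free-text unit tag, e.g. `"days"` or `"months"`.
#' @return A `data.frame` of class `"survival_table"`.
#' @export
survival_table <- function(sample_id, time, event, ..., time_unit = "days") {
  sample_id <- trimws(as.character(sample_id))
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (anyDuplicated(sample_id)) stopf("duplicate sample identifiers")
  if (any(!is.finite(time)) || any(time < 0)) stopf("survival times must be finite and >= 0")
  if (!all(event %in% c(0, 1))) stopf("event indicator must be 0 or 1")
  out <- data.frame(sample_id = sample_id, time = time, event = event,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) {
    if (length(extra[[nm]]) != nrow(out)) stopf("covariate '%s' has wrong length", nm)
    out[[nm]] <- extra[[nm]]
  }
  attr(out, "time_unit") <- time_unit
  class(out) <- c("survival_table", "data.frame")
  out
}
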