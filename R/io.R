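# Readers and writers for the plain-text formats the pipeline exchanges:
# expression tables (TSV/CSV, genes as rows), GMT gene sets, and clinical
# tables. Probe-level rows sharing a gene symbol are collapsed to per-gene
# medians on read, mirroring how multi-probe microarray data are summarized
# before deconvolution.

#' Read an expression matrix from a delimited file
#'
#' The first column holds gene identifiers, the header row sample
#' identifiers, and the body numeric expression values. Rows sharing a gene
#' symbol (multiple probes per gene) are collapsed to their per-sample
#' median via [collapse_duplicate_genes()].
#'
#' @param path File path.
#' @param fmt `"tsv"` or `"csv"`.
#' @param scale Declared expression scale, `"linear"` or `"log2"`.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, fmt = c("tsv", "csv"),
                                   scale = c("linear", "log2")) {
  fmt <- match.arg(fmt)
  scale <- match.arg(scale)
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (fmt == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) stopf("empty expression matrix in %s", path)
  genes <- trimws(raw[[1L]])
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body),
                                  dimnames = dimnames(body)))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stopf("non-numeric value '%s' at row %d (gene '%s'), column '%s'",
          body[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L], genes[bad[1L, 1L]],
          colnames(body)[bad[1L, 2L]])
  }
  rownames(vals) <- genes
  vals <- collapse_duplicate_genes(vals)
  expression_matrix(vals, scale = scale)
}

#' Write an expression matrix to a delimited file
#'
#' @param expr An expression matrix.
#' @param path Output path.
#' @param fmt `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path, fmt = c("tsv", "csv")) {
  fmt <- match.arg(fmt)
  sep <- if (fmt == "tsv") "\t" else ","
  df <- data.frame(gene = rownames(expr), as.data.frame(unclass_expr(expr)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse duplicate gene rows to per-gene medians
#'
#' Each output row is the per-sample median of all input rows carrying the
#' same gene symbol (the standard probe-to-gene summary for microarray
#' data); even counts use the mean of the two middle values. The operation
#' is idempotent and preserves the first-occurrence order of symbols.
#'
#' @param values Numeric matrix with (possibly duplicated) gene rownames,
#'   or an [expression_matrix()].
#' @return Matrix with one row per gene symbol. If the input was an
#'   `expr_matrix` the class and scale are preserved.
#' @export
collapse_duplicate_genes <- function(values) {
  was_expr <- inherits(values, "expr_matrix")
  scale <- expr_scale(values)
  m <- if (was_expr) unclass_expr(values) else as.matrix(values)
  genes <- trimws(rownames(m))
  if (is.null(genes)) stopf("matrix has no gene rownames")
  if (!anyDuplicated(genes)) {
    rownames(m) <- genes
    return(if (was_expr) expression_matrix(m, scale) else m)
  }
  keep <- unique(genes)
  idx <- split(seq_along(genes), factor(genes, levels = keep))
  out <- do.call(rbind, lapply(idx, function(i) {
    if (length(i) == 1L) m[i, , drop = FALSE]
    else matrix(apply(m[i, , drop = FALSE], 2L, stats::median), nrow = 1L)
  }))
  dimnames(out) <- list(keep, colnames(m))
  if (was_expr) expression_matrix(out, scale) else out
}

#' Read gene sets in GMT format
#'
#' One set per line: `name TAB description TAB gene1 TAB gene2 ...`.
#'
#' @param path File path.
#' @return A [gene_set_collection()] with per-set deduplicated gene lists,
#'   input order preserved.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("empty GMT file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stopf("GMT format error at line %d: fewer than 3 tab-separated fields",
          short[1L])
  }
  nms <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  gene_set_collection(sets, descriptions = desc)
}

#' Write gene sets in GMT format
#'
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Cohort spellings of cytogenetic risk mapped onto the three-level
# vocabulary used throughout.
.risk_aliases <- c(
  "FavorableOrIntermediate" = "Favorable",
  "IntermediateOrAdverse"   = "Intermediate",
  "Adverse"                 = "Poor",
  "Favorable"               = "Favorable",
  "Intermediate"            = "Intermediate",
  "Poor"                    = "Poor"
)

#' Read a clinical table
#'
#' Expects a delimited table with at least `sample_id`, `time` and `event`
#' columns. Rows with missing time or event are dropped (the number dropped
#' is reported via message and the `n_dropped` attribute); cytogenetic-risk
#' levels are normalized ("FavorableOrIntermediate" to "Favorable",
#' "IntermediateOrAdverse" to "Intermediate", "Adverse" to "Poor"). Missing
#' covariates are tolerated; only time and event are mandatory.
#'
#' @param path File path.
#' @param fmt `"tsv"` or `"csv"`.
#' @param time_unit Unit tag recorded on the result.
#' @return A [survival_table()] with attribute `n_dropped`.
#' @export
read_clinical_table <- function(path, fmt = c("tsv", "csv"), time_unit = "days") {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (fmt == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stopf("clinical table lacks column(s): %s", paste(miss, collapse = ", "))
  n_in <- nrow(df)
  keep <- !is.na(df$time) & !is.na(df$event)
  dropped <- n_in - sum(keep)
  if (dropped > 0L) message(sprintf("dropped %d row(s) with missing time/event", dropped))
  df <- df[keep, , drop = FALSE]
  if (any(df$time < 0)) stopf("negative survival time in %s", path)
  if (!all(df$event %in% c(0, 1))) stopf("event indicator outside {0,1} in %s", path)
  if ("cytogenetic_risk" %in% colnames(df)) {
    risk <- as.character(df$cytogenetic_risk)
    known <- !is.na(risk) & risk %in% names(.risk_aliases)
    risk[known] <- .risk_aliases[risk[known]]
    df$cytogenetic_risk <- risk
  }
  extra <- setdiff(colnames(df), need)
  out <- do.call(survival_table,
                 c(list(sample_id = df$sample_id, time = df$time, event = df$event,
                        time_unit = time_unit),
                   as.list(df[extra])))
  attr(out, "n_dropped") <- dropped
  out
}

#' Write a clinical table
#'
#' @param surv A [survival_table()].
#' @param path Output path.
#' @param fmt `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(surv, path, fmt = c("tsv", "csv")) {
  fmt <- match.arg(fmt)
  sep <- if (fmt == "tsv") "\t" else ","
  utils::write.table(as.data.frame(surv), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
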