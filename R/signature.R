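# Signature-matrix construction: one-vs-rest differential expression on
# log2-scale sorted profiles (empirical-Bayes moderated t via limma, or an
# ordinary pooled two-sample t), marker selection by log2FC and BH-adjusted
# p thresholds with per-type overrides and a top-N cap, and assembly of the
# marker x cell-type matrix of linear-scale median expression that
# deconvolution consumes.

#' One-vs-rest differential expression across cell types
#'
#' For every cell type, each gene is tested for elevated expression in that
#' type versus all remaining samples. `log2fc` is the mean log2 expression
#' in the type minus the mean in the rest. With `moderation =
#' "eb_moderated"` the t-statistic uses the empirical-Bayes shrunken
#' variance of limma's `lmFit`/`eBayes`; `"ordinary"` uses the pooled
#' two-sample t (constant genes get t = 0, p = 1). P-values are two-sided
#' and BH-adjusted within each cell type.
#'
#' @param profiles Log2-scale [expression_matrix()] of sorted samples.
#' @param labels [cell_type_labels()]; every type needs >= 2 replicates and
#'   >= 2 samples in the rest.
#' @param moderation `"eb_moderated"` (default) or `"ordinary"`.
#' @return A data.frame with columns `gene`, `cell_type`, `log2fc`,
#'   `t_stat`, `p_value`, `adj_p`.
#' @export
differential_expression_one_vs_rest <- function(profiles, labels,
                                                moderation = c("eb_moderated",
                                                               "ordinary")) {
  moderation <- match.arg(moderation)
  if (expr_scale(profiles) != "log2") {
    stopf("differential expression requires log2-scale profiles; use to_log2()")
  }
  validate_labels(labels, profiles, min_reps = 2L)
  types <- unique(labels)
  m <- unclass_expr(profiles)[, names(labels), drop = FALSE]
  out <- lapply(types, function(type) {
    in_type <- labels == type
    if (sum(!in_type) < 2L) stopf("cell type '%s' leaves fewer than 2 rest samples", type)
    x <- m[, in_type, drop = FALSE]; y <- m[, !in_type, drop = FALSE]
    n1 <- ncol(x); n2 <- ncol(y)
    lfc <- rowMeans(x) - rowMeans(y)
    v1 <- apply(x, 1L, stats::var); v2 <- apply(y, 1L, stats::var)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    # zero residual variance: a nonzero group difference is then infinitely
    # well supported (p = 0); a constant gene carries no evidence (p = 1)
    degen <- sp2 <= 0
    tstat <- rep(NA_real_, nrow(m)); pval <- rep(NA_real_, nrow(m))
    tstat[degen] <- ifelse(lfc[degen] != 0, sign(lfc[degen]) * Inf, 0)
    pval[degen] <- ifelse(lfc[degen] != 0, 0, 1)
    if (any(!degen)) {
      if (moderation == "eb_moderated") {
        design <- cbind(Intercept = 1, group = as.numeric(in_type))
        fit <- limma::eBayes(limma::lmFit(m[!degen, , drop = FALSE], design))
        tstat[!degen] <- fit$t[, "group"]
        pval[!degen] <- fit$p.value[, "group"]
      } else {
        se <- sqrt(sp2[!degen] * (1 / n1 + 1 / n2))
        tstat[!degen] <- lfc[!degen] / se
        pval[!degen] <- 2 * stats::pt(-abs(tstat[!degen]), df = n1 + n2 - 2)
      }
    }
    data.frame(gene = rownames(m), cell_type = type, log2fc = lfc,
               t_stat = tstat, p_value = pval,
               adj_p = stats::p.adjust(pval, method = "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Select marker genes per cell type
#'
#' Markers for a type are the genes with `log2fc >= logfc_min` and
#' `adj_p <= threshold(type)`, sorted by descending log2fc (ties broken by
#' ascending adjusted p, then gene id) and truncated to `top_n`. Per-type
#' threshold overrides accommodate sparse populations that would otherwise
#' yield too few markers.
#'
#' @param degs Output of [differential_expression_one_vs_rest()].
#' @param logfc_min Minimum log2 fold change (default 1).
#' @param adjp_default Default BH-adjusted p threshold (default 0.05).
#' @param adjp_overrides Named numeric vector of per-type thresholds, e.g.
#'   `c(LSC = 0.1, RApos = 0.1, MPP = 0.2)`.
#' @param top_n Cap on markers per type (default 150).
#' @return Named list (per cell type) of ordered marker gene vectors.
#' @export
select_marker_genes <- function(degs, logfc_min = 1, adjp_default = 0.05,
                                adjp_overrides = NULL, top_n = 150L) {
  if (any(c(adjp_default, adjp_overrides) <= 0) ||
      any(c(adjp_default, adjp_overrides) > 1)) {
    stopf("adjusted-p thresholds must lie in (0, 1]")
  }
  if (top_n < 1L) stopf("top_n must be >= 1")
  types <- unique(degs$cell_type)
  unknown <- setdiff(names(adjp_overrides), types)
  if (length(unknown)) stopf("adjp override for unknown cell type: %s",
                             paste(unknown, collapse = ", "))
  thresholds <- stats::setNames(rep(adjp_default, length(types)), types)
  thresholds[names(adjp_overrides)] <- adjp_overrides
  out <- lapply(types, function(type) {
    d <- degs[degs$cell_type == type & degs$log2fc >= logfc_min &
                degs$adj_p <= thresholds[[type]], , drop = FALSE]
    d <- d[order(-d$log2fc, d$adj_p, d$gene), , drop = FALSE]
    utils::head(d$gene, top_n)
  })
  stats::setNames(out, types)
}

#' Assemble a signature matrix from marker lists
#'
#' The row set is the union of the per-type marker lists (`shared_policy =
#' "keep"`) or that union minus genes selected for more than one type
#' (`"drop_shared"`); genes appearing in multiple lists are recorded as
#' `shared_genes` either way. Cell values are per-type medians of
#' linear-scale expression across the sorted replicates (log2 profiles are
#' exponentiated first), the scale on which mixtures are additive.
#'
#' @param profiles Reference [expression_matrix()] (any scale).
#' @param labels [cell_type_labels()] for the profile columns.
#' @param marker_lists Named per-type list from [select_marker_genes()].
#' @param shared_policy `"keep"` (default) or `"drop_shared"`.
#' @return A list of class `"signature_matrix"` with elements `values`
#'   (marker genes x cell types, linear scale), `marker_lists`,
#'   `shared_genes` and `cell_types`.
#' @export
build_signature_matrix <- function(profiles, labels, marker_lists,
                                   shared_policy = c("keep", "drop_shared")) {
  shared_policy <- match.arg(shared_policy)
  validate_labels(labels, profiles, min_reps = 1L)
  all_markers <- unlist(marker_lists, use.names = FALSE)
  missing <- setdiff(all_markers, rownames(profiles))
  if (length(missing)) stopf("marker(s) absent from profiles: %s",
                             paste(utils::head(missing, 5L), collapse = ", "))
  shared <- sort(unique(all_markers[duplicated(all_markers)]))
  rows <- unique(all_markers)
  if (shared_policy == "drop_shared") rows <- setdiff(rows, shared)
  if (length(rows) == 0L) stopf("signature matrix would be empty")
  M <- celltype_median_profiles(profiles, labels)
  types <- intersect(unique(labels), names(marker_lists))
  structure(list(values = M[rows, types, drop = FALSE],
                 marker_lists = marker_lists[types],
                 shared_genes = shared, cell_types = types,
                 shared_policy = shared_policy),
            class = "signature_matrix")
}

#' @export
#' @method print signature_matrix
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature matrix: %d marker genes x %d cell types (policy: %s)\n",
              nrow(x$values), length(x$cell_types), x$shared_policy))
  counts <- vapply(x$marker_lists, length, 0L)
  cat("markers per type:\n")
  print(counts)
  cat(sprintf("genes shared by >1 type: %d\n", length(x$shared_genes)))
  invisible(x)
}
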