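# Single-sample gene-set enrichment and its downstream analyses. The
# enrichment score follows the GSVA construction: a per-gene kernel-CDF
# statistic across samples (Gaussian kernel, bandwidth sd/4, or a Poisson
# kernel for counts), per-sample gene ranking, the symmetric rank
# statistic |position - p/2| along the decreasing-score order, and a
# weighted Kolmogorov-Smirnov-like random walk whose inside-set increments
# are |rank statistic|^tau (normalized) and outside-set decrements
# 1/(p - set size). Downstream: k-medoids (PAM) clustering of enrichment
# profiles, Fisher's exact concordance between binary groupings,
# score/gene-set Pearson correlation matrices, and moderated-t group-wise
# enrichment differences.

# Per-gene kernel CDF statistic across samples. Rows with zero spread get
# a flat 0.5 (no evidence either way).
kernel_cdf_scores <- function(m, kcdf = c("gaussian", "poisson")) {
  kcdf <- match.arg(kcdf)
  z <- matrix(0.5, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
  n <- ncol(m)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (kcdf == "gaussian") {
      h <- stats::sd(x) / 4
      if (h == 0) next
      z[i, ] <- rowMeans(stats::pnorm(outer(x, x, "-") / h))
    } else {
      lam <- pmax(x, 0) + 0.5
      z[i, ] <- colMeans(stats::ppois(matrix(rep(x, each = n), nrow = n),
                                      lambda = lam))
    }
  }
  z
}

# Weighted KS random walk for one sample. ord: gene indices in decreasing
# score order; w: |symmetric rank statistic|^tau per gene (walk order);
# inset: logical per gene in walk order.
ks_walk_es <- function(w, inset, mode) {
  m <- sum(inset)
  p <- length(inset)
  dec <- 1 / (p - m)
  step <- ifelse(inset, w / sum(w[inset]), -dec)
  v <- cumsum(step)
  if (mode == "max_diff") {
    max(c(0, v)) + min(c(0, v))
  } else {
    v[which.max(abs(v))]
  }
}

#' GSVA-style single-sample enrichment scores
#'
#' For each sample and gene set, computes an enrichment score from a
#' weighted KS-like random walk over the sample's kernel-CDF-ranked gene
#' list (see the package source header of this module for the exact
#' construction). `mode = "max_diff"` reports the sum of the maximum
#' positive and maximum negative walk deviations; `"max_dev"` the single
#' largest-magnitude deviation. Sets with no genes in the matrix are
#' skipped (recorded in the `skipped_sets` attribute), not an error.
#'
#' @param expr An [expression_matrix()] (log2 recommended with the
#'   Gaussian kernel; counts with the Poisson kernel); >= 3 samples.
#' @param sets A [gene_set_collection()].
#' @param kcdf Kernel for the per-gene CDF: `"gaussian"` or `"poisson"`.
#' @param tau Weight exponent on the rank statistic (default 1).
#' @param mode `"max_diff"` (default) or `"max_dev"`.
#' @return Gene-sets x samples numeric matrix of enrichment scores with
#'   attributes `valid_genes` (per-set gene counts used) and
#'   `skipped_sets`.
#' @export
gsva_scores <- function(expr, sets, kcdf = c("gaussian", "poisson"),
                        tau = 1, mode = c("max_diff", "max_dev")) {
  kcdf <- match.arg(kcdf)
  mode <- match.arg(mode)
  if (ncol(expr) < 3L) stopf("kernel CDF estimation needs >= 3 samples")
  m <- unclass_expr(expr)
  genes <- rownames(m)
  valid <- lapply(sets, function(g) intersect(g, genes))
  skipped <- names(valid)[lengths(valid) == 0L]
  used <- setdiff(names(valid), skipped)
  p <- nrow(m)
  if (any(lengths(valid[used]) >= p)) {
    stopf("a gene set covers every gene in the matrix; no outside-set genes remain")
  }
  z <- kernel_cdf_scores(m, kcdf)
  es <- matrix(NA_real_, nrow = length(used), ncol = ncol(m),
               dimnames = list(used, colnames(m)))
  for (j in seq_len(ncol(m))) {
    # decreasing kernel-CDF score; ties broken by stable gene order
    ord <- order(z[, j], decreasing = TRUE)
    w <- abs(seq_len(p) - p / 2) ^ tau
    member <- lapply(valid[used], function(g) genes[ord] %in% g)
    for (k in seq_along(used)) {
      es[k, j] <- ks_walk_es(w, member[[k]], mode)
    }
  }
  attr(es, "valid_genes") <- lengths(valid[used])
  attr(es, "skipped_sets") <- skipped
  es
}

#' Cluster samples by partitioning around medoids
#'
#' k-medoids clustering of enrichment profiles (samples described by their
#' per-set scores) via the BUILD + SWAP algorithm of `cluster::pam`.
#' Medoids are actual samples; the procedure is deterministic for a given
#' input.
#'
#' @param es Gene-sets x samples score matrix (e.g. from [gsva_scores()]).
#' @param k Number of clusters (default 2).
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson r between sample profiles).
#' @return List with `labels` (named cluster ids per sample), `medoids`
#'   (sample ids) and `objective` (total within-cluster distance to
#'   medoids).
#' @export
pam_cluster <- function(es, k = 2L, distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  k <- as.integer(k)
  if (k <= 0L) stopf("k must be positive")
  if (k >= ncol(es)) stopf("k must be smaller than the number of samples")
  d <- if (distance == "euclidean") {
    stats::dist(t(es))
  } else {
    stats::as.dist(1 - stats::cor(es))
  }
  fit <- cluster::pam(d, k = k, diss = TRUE)
  list(labels = stats::setNames(as.integer(fit$clustering), colnames(es)),
       medoids = colnames(es)[fit$id.med],
       objective = sum(fit$clusinfo[, "av_diss"] * fit$clusinfo[, "size"]))
}

#' Concordance of two binary groupings by Fisher's exact test
#'
#' Cross-tabulates the labels and tests association with the two-sided
#' Fisher exact test (probability-mass-at-most-observed convention); the
#' odds ratio is the conditional MLE. A constant labeling yields a
#' degenerate table: p = 1 with a warning.
#'
#' @param labelsA,labelsB Binary labels over the same samples (named
#'   vectors are aligned on names).
#' @return List of class `"concordance_result"`: `table` (2x2),
#'   `odds_ratio`, `p`.
#' @export
fisher_concordance <- function(labelsA, labelsB) {
  if (!is.null(names(labelsA)) && !is.null(names(labelsB))) {
    common <- intersect(names(labelsA), names(labelsB))
    if (length(common) == 0L) stopf("no shared samples")
    labelsA <- labelsA[common]; labelsB <- labelsB[common]
  }
  if (length(labelsA) != length(labelsB)) stopf("label vectors differ in length")
  fA <- factor(labelsA); fB <- factor(labelsB)
  if (nlevels(fA) < 2L || nlevels(fB) < 2L) {
    warnf("degenerate table: a labeling is constant; p = 1")
    return(structure(list(table = table(fA, fB), odds_ratio = NA_real_, p = 1),
                     class = "concordance_result"))
  }
  if (nlevels(fA) != 2L || nlevels(fB) != 2L) stopf("labels must be binary")
  tab <- table(fA, fB)
  ft <- stats::fisher.test(tab)
  structure(list(table = tab, odds_ratio = unname(ft$estimate), p = ft$p.value),
            class = "concordance_result")
}

#' @export
#' @method print concordance_result
print.concordance_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("odds ratio (conditional MLE): %.4g\ntwo-sided Fisher p: %.3g\n",
              x$odds_ratio, x$p))
  invisible(x)
}

#' Correlation matrix of enrichment scores and prognostic scores
#'
#' Stacks gene-set enrichment rows with one or more score vectors and
#' computes all pairwise Pearson correlations, two-sided p-values via the
#' t transform, and BH adjustment across the upper triangle. Significance
#' tiers: `*`, `**`, `***` for adjusted p at or below 0.05, 0.01, 0.001.
#'
#' @param es Gene-sets x samples score matrix.
#' @param scores A named list of score tables / named numeric vectors to
#'   append as extra rows (e.g. `list(LSCA = score_table)`).
#' @return List with matrices `r`, `p`, `adj_p` and `stars` (character).
#'   Zero-variance rows give `NA` entries.
#' @export
score_geneset_correlations <- function(es, scores) {
  samples <- colnames(es)
  extra <- do.call(rbind, lapply(names(scores), function(nm) {
    score_vector(scores[[nm]], samples)
  }))
  rownames(extra) <- names(scores)
  mat <- rbind(es, extra)
  n <- ncol(mat)
  sds <- apply(mat, 1L, stats::sd)
  r <- suppressWarnings(stats::cor(t(mat)))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  diag(p) <- NA
  adj_p <- p
  up <- upper.tri(p)
  adj_p[up] <- stats::p.adjust(p[up], method = "BH")
  adj_p[lower.tri(adj_p)] <- t(adj_p)[lower.tri(adj_p)]
  stars <- matrix("", nrow = nrow(p), ncol = ncol(p), dimnames = dimnames(p))
  stars[!is.na(adj_p) & adj_p <= 0.05] <- "*"
  stars[!is.na(adj_p) & adj_p <= 0.01] <- "**"
  stars[!is.na(adj_p) & adj_p <= 0.001] <- "***"
  list(r = r, p = p, adj_p = adj_p, stars = stars)
}

#' Group-wise enrichment-score differences
#'
#' Per gene set, the difference of mean enrichment between the high and
#' low groups (`es_diff`, reported where a fold change would be on
#' expression data; ES values are signed, so a literal ratio is
#' undefined), a moderated-t p-value (limma across sets; ordinary t when
#' only one set is available) and BH adjustment. Sets skipped upstream for
#' lack of valid genes are reported as missing.
#'
#' @param es Gene-sets x samples score matrix from [gsva_scores()].
#' @param groups high/low labels over the samples (named vector aligned on
#'   sample ids, or a split `"score_table"` with a `group` column).
#' @return A data.frame: `set`, `es_diff`, `p`, `adj_p`, `skipped`.
#' @export
groupwise_es_difference <- function(es, groups) {
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group), groups$sample_id)
  }
  if (!is.null(names(groups))) {
    miss <- setdiff(colnames(es), names(groups))
    if (length(miss)) stopf("group label missing for sample(s): %s",
                            paste(utils::head(miss, 5L), collapse = ", "))
    groups <- groups[colnames(es)]
  }
  g <- factor(groups, levels = c("low", "high"))
  if (any(table(g) == 0L) || nlevels(g) != 2L) {
    stopf("both 'high' and 'low' groups must be non-empty")
  }
  high <- g == "high"
  diff <- rowMeans(es[, high, drop = FALSE]) - rowMeans(es[, !high, drop = FALSE])
  if (nrow(es) >= 2L) {
    design <- cbind(Intercept = 1, high = as.numeric(high))
    fit <- limma::eBayes(limma::lmFit(es, design))
    p <- fit$p.value[, "high"]
  } else {
    p <- stats::t.test(es[1L, high], es[1L, !high], var.equal = TRUE)$p.value
  }
  out <- data.frame(set = rownames(es), es_diff = unname(diff), p = unname(p),
                    adj_p = stats::p.adjust(p, method = "BH"),
                    skipped = FALSE, stringsAsFactors = FALSE, row.names = NULL)
  skipped <- attr(es, "skipped_sets")
  if (length(skipped)) {
    out <- rbind(out, data.frame(set = skipped, es_diff = NA_real_, p = NA_real_,
                                 adj_p = NA_real_, skipped = TRUE,
                                 stringsAsFactors = FALSE))
  }
  out
}
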