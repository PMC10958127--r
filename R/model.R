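# The LSCA score model: L1-penalized Cox regression of survival on
# cell-type fractions (glmnet), 10-fold cross-validated lambda selection,
# and a 100-iteration stability-selection wrapper that filters out cell
# types whose coefficient is shrunk exactly to zero in more than
# `zero_limit` iterations and averages the per-iteration coefficients of
# the survivors. lsca() is the user-facing fitter; the fitted object
# carries coef/predict/print/summary/plot methods.

align_survival <- function(X, survival) {
  stopifnot(is.matrix(X))
  if (is.null(rownames(X))) stopf("fraction matrix needs sample rownames")
  miss <- setdiff(rownames(X), survival$sample_id)
  if (length(miss)) stopf("sample(s) missing from survival table: %s",
                          paste(utils::head(miss, 5L), collapse = ", "))
  survival[match(rownames(X), survival$sample_id), , drop = FALSE]
}

#' Fit an L1-penalized Cox model at a fixed penalty
#'
#' Maximizes the lasso-penalized Cox partial log-likelihood (Breslow tie
#' handling) by glmnet's cyclic coordinate descent; coefficients at the
#' requested `lambda` are computed exactly along the regularization path.
#' Fractions enter unstandardized: they already share the `[0, 1]` scale.
#'
#' @param X Samples x features numeric matrix (e.g. cell-type fractions),
#'   rownames = sample ids.
#' @param survival A [survival_table()] covering the rows of `X`.
#' @param lambda Penalty value (>= 0).
#' @param standardize Standardize columns before fitting (default FALSE).
#' @return Named numeric coefficient vector (exact zeros possible).
#' @export
fit_lasso_cox <- function(X, survival, lambda, standardize = FALSE) {
  if (!all(is.finite(X))) stopf("non-finite values in feature matrix")
  sv <- align_survival(X, survival)
  if (sum(sv$event) < 1) stopf("no events in survival data")
  y <- survival::Surv(sv$time, sv$event)
  fit <- glmnet::glmnet(X, y, family = "cox", standardize = standardize,
                        thresh = 1e-12)
  co <- glmnet::coef.glmnet(fit, s = lambda, exact = TRUE, x = X, y = y,
                            standardize = standardize, thresh = 1e-12)
  stats::setNames(as.numeric(co), rownames(co))
}

#' Select the Cox lasso penalty by cross-validation
#'
#' Ten-fold (by default) cross-validation over glmnet's log-spaced lambda
#' grid, scoring each lambda by mean held-out partial-likelihood deviance;
#' `lambda_min` is the minimizer. Fold assignment is seeded and re-drawn
#' (up to `max_retry` times) until every fold contains at least one event.
#'
#' @param X Samples x features matrix.
#' @param survival A [survival_table()].
#' @param n_folds Number of CV folds (default 10).
#' @param lambda_grid Optional explicit lambda sequence (descending).
#' @param seed RNG seed for fold assignment.
#' @param standardize Standardize columns (default FALSE).
#' @param max_retry Fold re-randomization attempts (default 25).
#' @return A list of class `"lasso_cox_cv"`: `lambda_grid`, `cv_deviance`,
#'   `lambda_min`, `coefficients` (at `lambda_min`), `foldid`.
#' @export
cv_select_lambda <- function(X, survival, n_folds = 10L, lambda_grid = NULL,
                             seed = 1L, standardize = FALSE, max_retry = 25L) {
  sv <- align_survival(X, survival)
  n <- nrow(X)
  if (n_folds > n) stopf("more folds than samples")
  if (sum(sv$event) < n_folds) {
    stopf("fewer events (%d) than folds (%d); reduce n_folds", sum(sv$event), n_folds)
  }
  foldid <- NULL
  for (try in seq_len(max_retry)) {
    cand <- with_seed(derive_seed(seed, try - 1L),
                      sample(rep_len(seq_len(n_folds), n)))
    if (all(tapply(sv$event, cand, sum) >= 1)) { foldid <- cand; break }
  }
  if (is.null(foldid)) {
    stopf("could not place an event in every fold after %d tries; use fewer folds",
          max_retry)
  }
  y <- survival::Surv(sv$time, sv$event)
  cvfit <- glmnet::cv.glmnet(X, y, family = "cox", foldid = foldid,
                             lambda = lambda_grid, standardize = standardize,
                             type.measure = "deviance")
  co <- glmnet::coef.glmnet(cvfit$glmnet.fit, s = cvfit$lambda.min)
  structure(list(lambda_grid = cvfit$lambda, cv_deviance = cvfit$cvm,
                 lambda_min = cvfit$lambda.min,
                 coefficients = stats::setNames(as.numeric(co), rownames(co)),
                 foldid = foldid),
            class = "lasso_cox_cv")
}

#' Fit the LSCA score model by stability-selected lasso Cox regression
#'
#' Repeats cross-validated lasso Cox regression `n_iter` times (each
#' iteration re-randomizes the CV folds from an iteration-derived seed;
#' with `resample = TRUE` patients are additionally bootstrap-resampled),
#' recording the coefficient vector at each iteration's `lambda_min`. Cell
#' types whose coefficient is exactly zero in more than `zero_limit`
#' iterations are filtered out; each retained type's final coefficient is
#' the mean of its coefficients over all iterations (zeros included), with
#' no refit after filtering.
#'
#' A sample's score is then the inner product of its fraction vector with
#' the retained coefficients (see [predict.lsca()] / [compute_score()]).
#'
#' @param fractions Samples x cell-types fraction matrix.
#' @param survival A [survival_table()] covering the samples.
#' @param n_iter Number of stability iterations (default 100).
#' @param zero_limit A type is dropped when its coefficient is zero in
#'   strictly more than this many iterations (default 5).
#' @param n_folds CV folds per iteration (default 10).
#' @param seed Master seed.
#' @param resample Bootstrap-resample patients each iteration instead of
#'   only re-randomizing folds (default FALSE).
#' @param standardize Standardize fractions before fitting (default FALSE).
#' @return An object of class `"lsca"`: `coefficients` (retained types),
#'   `zero_counts`, `per_iteration` (n_iter x types coefficient record),
#'   `n_iter`, `zero_limit`, `cell_types`, `lambda_min` (per iteration).
#' @export
lsca <- function(fractions, survival, n_iter = 100L, zero_limit = 5L,
                 n_folds = 10L, seed = 1L, resample = FALSE,
                 standardize = FALSE) {
  X <- as.matrix(fractions)
  sv <- align_survival(X, survival)
  K <- ncol(X)
  per_iter <- matrix(NA_real_, nrow = n_iter, ncol = K,
                     dimnames = list(NULL, colnames(X)))
  lambdas <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, 100L + i)
    if (resample) {
      idx <- with_seed(derive_seed(it_seed, 7L), {
        repeat {
          cand <- sample.int(nrow(X), replace = TRUE)
          if (sum(sv$event[cand]) >= n_folds) break
        }
        cand
      })
      Xi <- X[idx, , drop = FALSE]
      rownames(Xi) <- sprintf("b%05d", seq_along(idx))
      svi <- sv[idx, , drop = FALSE]
      svi$sample_id <- rownames(Xi)
      class(svi) <- class(sv)
    } else {
      Xi <- X; svi <- sv
    }
    cv <- cv_select_lambda(Xi, svi, n_folds = n_folds, seed = it_seed,
                           standardize = standardize)
    per_iter[i, names(cv$coefficients)] <- cv$coefficients
    lambdas[i] <- cv$lambda_min
  }
  flt <- stability_filter(per_iter, zero_limit)
  zero_counts <- flt$zero_counts
  retained <- flt$retained
  structure(list(coefficients = colMeans(per_iter)[retained],
                 zero_counts = zero_counts, per_iteration = per_iter,
                 n_iter = as.integer(n_iter), zero_limit = as.integer(zero_limit),
                 cell_types = colnames(X), lambda_min = lambdas,
                 provenance = "fitted", call = match.call()),
            class = "lsca")
}

#' @rdname lsca
#' @param ... Passed through to [lsca()].
#' @export
stability_select <- function(fractions, survival, ...) {
  lsca(fractions, survival, ...)
}

# The drop rule of the stability wrapper: a cell type survives iff its
# coefficient was exactly zero in at most `zero_limit` iterations
# ("more than `zero_limit` times" drops, strictly).
stability_filter <- function(per_iter, zero_limit) {
  zero_counts <- colSums(per_iter == 0)
  retained <- names(zero_counts)[zero_counts <= zero_limit]
  if (length(retained) == 0L) {
    stopf("all cell types filtered out; zero counts: %s",
          paste(sprintf("%s=%d", names(zero_counts), zero_counts), collapse = ", "))
  }
  list(zero_counts = zero_counts, retained = retained)
}

#' The published LSCA coefficient model
#'
#' The leukemic stem cell activity score as published:
#' `LSCA = -2.15 * F_GMP - 1.64 * F_CMP + 0.37 * F_RApos + 0.49 * F_MEP
#' + 4.52 * F_MPP`. Use it with [compute_score()] / [predict.lsca()] to
#' score cohorts whose fractions were deconvoluted against a nine-type
#' hematopoietic signature.
#'
#' @return An object of class `"lsca"` carrying the published
#'   coefficients (no per-iteration record).
#' @export
lsca_paper_model <- function() {
  structure(list(coefficients = c(GMP = -2.15, CMP = -1.64, RApos = 0.37,
                                  MEP = 0.49, MPP = 4.52),
                 zero_counts = NULL, per_iteration = NULL,
                 n_iter = NA_integer_, zero_limit = NA_integer_,
                 cell_types = hemlin9_cell_types(), lambda_min = NULL,
                 provenance = "published"),
            class = "lsca")
}

#' Score samples with an LSCA model
#'
#' `score(sample) = sum_c beta_c * F_c(sample)` over the model's retained
#' cell types; fraction columns outside the model are ignored.
#'
#' @param model An `"lsca"` object.
#' @param fractions Samples x cell-types fraction matrix containing every
#'   model cell type.
#' @return A data.frame (`sample_id`, `score`) of class `"score_table"`.
#' @export
compute_score <- function(model, fractions) {
  stopifnot(inherits(model, "lsca"))
  fractions <- as.matrix(fractions)
  beta <- model$coefficients
  miss <- setdiff(names(beta), colnames(fractions))
  if (length(miss)) stopf("model cell type(s) absent from fractions: %s",
                          paste(miss, collapse = ", "))
  score <- drop(fractions[, names(beta), drop = FALSE] %*% beta)
  out <- data.frame(sample_id = rownames(fractions) %||% seq_along(score),
                    score = as.numeric(score), stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' Split scored samples into high and low groups
#'
#' Samples scoring strictly above the threshold (the median or mean score)
#' form the high group; the rest, including samples exactly at the
#' threshold, the low group. Median is the conventional split for the LSCA
#' score; the mean split suits single-cell-type abundances whose median
#' may be zero.
#'
#' @param scores A `"score_table"` from [compute_score()].
#' @param method `"median"` (default) or `"mean"`.
#' @return The score table with a `group` factor column (levels low, high)
#'   and attributes `threshold` and `group_counts`.
#' @export
split_by_threshold <- function(scores, method = c("median", "mean")) {
  method <- match.arg(method)
  if (nrow(scores) < 2L) stopf("need at least 2 samples to split")
  if (max(scores$score) == min(scores$score)) {
    stopf("all scores identical; no split possible")
  }
  thr <- if (method == "median") stats::median(scores$score) else mean(scores$score)
  scores$group <- factor(ifelse(scores$score > thr, "high", "low"),
                         levels = c("low", "high"))
  attr(scores, "threshold") <- thr
  attr(scores, "group_counts") <- table(scores$group)
  scores
}

#' @export
#' @method print lsca
print.lsca <- function(x, ...) {
  cat(sprintf("LSCA score model (%s)\n", x$provenance))
  cat("coefficients:\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$zero_counts)) {
    dropped <- setdiff(x$cell_types, names(x$coefficients))
    cat(sprintf("retained %d of %d cell types (zero_limit = %d, n_iter = %d)\n",
                length(x$coefficients), length(x$cell_types), x$zero_limit,
                x$n_iter))
    if (length(dropped)) cat("dropped:", paste(dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
#' @method summary lsca
summary.lsca <- function(object, ...) {
  cat(sprintf("LSCA score model (%s)\n\n", object$provenance))
  if (is.null(object$per_iteration)) {
    print(round(object$coefficients, 4))
    return(invisible(object))
  }
  tab <- data.frame(
    cell_type = colnames(object$per_iteration),
    mean_coef = colMeans(object$per_iteration),
    sd_coef = apply(object$per_iteration, 2L, stats::sd),
    zero_count = object$zero_counts,
    retained = colnames(object$per_iteration) %in% names(object$coefficients),
    row.names = NULL
  )
  print(tab, digits = 4)
  cat(sprintf("\n%d iterations, 10-fold CV; drop rule: zero in > %d iterations\n",
              object$n_iter, object$zero_limit))
  invisible(tab)
}

#' @export
#' @method coef lsca
coef.lsca <- function(object, ...) object$coefficients

#' Predict LSCA scores for new fraction data
#'
#' @param object An `"lsca"` model.
#' @param newdata Samples x cell-types fraction matrix.
#' @param ... Unused.
#' @return A `"score_table"` data.frame (see [compute_score()]).
#' @export
#' @method predict lsca
predict.lsca <- function(object, newdata, ...) compute_score(object, newdata)

#' Plot the per-iteration coefficient distribution of an LSCA fit
#'
#' @param x A fitted `"lsca"` object (with a per-iteration record).
#' @param ... Passed to [graphics::boxplot()].
#' @export
#' @method plot lsca
plot.lsca <- function(x, ...) {
  if (is.null(x$per_iteration)) {
    graphics::barplot(x$coefficients, ylab = "coefficient", ...)
    return(invisible(x))
  }
  graphics::boxplot(x$per_iteration, ylab = "coefficient per iteration",
                    las = 2, ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}
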