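# Survival validation of a sample score: Kaplan-Meier curves, the
# two-group log-rank test, multivariate Cox regression with Wald hazard
# ratios, and IPCW cumulative/dynamic time-dependent AUC with a paired
# bootstrap comparison test. The standard estimators are delegated to the
# survival package; the IPCW AUC is computed here.

resolve_groups <- function(survival, groups) {
  if (is.null(groups)) return(factor(rep("all", nrow(survival))))
  if (!is.null(names(groups))) groups <- groups[survival$sample_id]
  if (length(groups) != nrow(survival)) stopf("group labels do not match samples")
  if (anyNA(groups)) stopf("missing group label(s)")
  factor(groups)
}

#' Kaplan-Meier survival curves
#'
#' Product-limit estimator per group: `S(t) = prod_{t_i <= t} (1 - d_i /
#' n_i)`; censored subjects leave the risk set after their time.
#'
#' @param survival A [survival_table()].
#' @param groups Optional group labels (named by sample id, or in table
#'   order); `NULL` fits a single curve.
#' @return A data.frame of class `"km_curve"` with columns `group`,
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
kaplan_meier <- function(survival, groups = NULL) {
  g <- resolve_groups(survival, groups)
  if (any(table(g) == 0L)) stopf("empty group")
  d <- data.frame(time = survival$time, event = survival$event, group = g)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  strata <- if (is.null(fit$strata)) {
    rep(levels(g)[1L], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  out <- data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv, stringsAsFactors = FALSE)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Chi-squared statistic `(sum(O1 - E1))^2 / sum(V)` accumulating observed
#' minus expected events with hypergeometric variance at each distinct
#' event time; p from the chi-squared distribution with 1 df.
#'
#' @param survival A [survival_table()].
#' @param groups Binary group labels (named by sample id, or in order).
#' @return List with `chi2` and `p`.
#' @export
logrank_test <- function(survival, groups) {
  g <- resolve_groups(survival, groups)
  if (nlevels(g) != 2L) stopf("log-rank test needs exactly 2 non-empty groups")
  if (sum(survival$event) < 1) stopf("no events observed")
  d <- data.frame(time = survival$time, event = survival$event, group = g)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  chi2 <- unname(sd_$chisq)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards regression
#'
#' Efron tie handling; per covariate the hazard ratio `exp(beta)`, Wald
#' 95% CI `exp(beta +/- 1.96 se)` and Wald p-value. Categorical covariates
#' are expanded against declared reference levels (`sex` = Female,
#' `cytogenetic_risk` = Favorable by default).
#'
#' @param survival A [survival_table()] whose extra columns include the
#'   covariates.
#' @param covariates Character vector of covariate column names; may also
#'   name columns of `extra`.
#' @param extra Optional data.frame of additional per-sample columns
#'   (matched by `sample_id` or row order), e.g. a score column.
#' @param reference Named list of reference levels for categorical terms.
#' @return A data.frame of class `"cox_result"`: `term`, `beta`, `hr`,
#'   `ci_low`, `ci_high`, `se`, `p`.
#' @export
cox_multivariate <- function(survival, covariates, extra = NULL,
                             reference = list(sex = "Female",
                                              cytogenetic_risk = "Favorable")) {
  d <- as.data.frame(survival)
  if (!is.null(extra)) {
    extra <- as.data.frame(extra)
    if ("sample_id" %in% colnames(extra)) {
      extra <- extra[match(d$sample_id, extra$sample_id), , drop = FALSE]
      extra$sample_id <- NULL
    } else if (nrow(extra) != nrow(d)) stopf("`extra` rows do not match samples")
    d <- cbind(d, extra)
  }
  miss <- setdiff(covariates, colnames(d))
  if (length(miss)) stopf("covariate(s) not found: %s", paste(miss, collapse = ", "))
  for (cv in covariates) {
    if (is.character(d[[cv]]) || is.factor(d[[cv]])) {
      d[[cv]] <- factor(d[[cv]])
      ref <- reference[[cv]]
      if (!is.null(ref) && ref %in% levels(d[[cv]])) {
        d[[cv]] <- stats::relevel(d[[cv]], ref = ref)
      }
    }
    vals <- d[[cv]]
    if (length(unique(vals[!is.na(vals)])) < 2L) stopf("constant covariate '%s'", cv)
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = d, ties = "efron",
                         control = survival::coxph.control(iter.max = 100L))
  if (anyNA(stats::coef(fit))) {
    stopf("rank-deficient covariate matrix (aliased term(s): %s)",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  out <- data.frame(term = names(beta), beta = unname(beta),
                    hr = exp(unname(beta)),
                    ci_low = exp(unname(beta) - 1.96 * se),
                    ci_high = exp(unname(beta) + 1.96 * se),
                    se = unname(se),
                    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("cox_result", "data.frame")
  out
}

# KM estimator of the censoring survival function G(t) evaluated just
# before each requested time (left limit).
censoring_km_left <- function(time, event, at) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  vapply(at, function(t) {
    keep <- fit$time < t
    if (!any(keep)) 1 else min(fit$surv[keep])
  }, 0)
}

#' Time-dependent AUC with inverse-probability-of-censoring weights
#'
#' Cumulative/dynamic AUC(t): cases are subjects with an observed event at
#' or before `t`, controls those still under observation beyond `t`.
#' Case contributions are weighted by `1 / G(T_i-)`, the Kaplan-Meier
#' estimate of the censoring survival function just before the case's
#' event time, which removes the bias censoring induces. With no
#' censoring the estimate reduces to the Mann-Whitney statistic of scores
#' for cases versus controls; ties in score count one half.
#'
#' @param scores A `"score_table"` (columns `sample_id`, `score`) or a
#'   named numeric vector.
#' @param survival A [survival_table()].
#' @param times Evaluation times.
#' @return A data.frame of class `"timed_auc"`: `time`, `auc`, `n_cases`,
#'   `n_controls`. `auc` is `NA` when either class is empty at `t`.
#' @export
time_dependent_auc <- function(scores, survival, times) {
  s <- score_vector(scores, survival$sample_id)
  out <- data.frame(time = times, auc = NA_real_, n_cases = 0L, n_controls = 0L)
  for (i in seq_along(times)) {
    t <- times[i]
    case <- survival$time <= t & survival$event == 1
    ctrl <- survival$time > t
    out$n_cases[i] <- sum(case); out$n_controls[i] <- sum(ctrl)
    if (!any(case) || !any(ctrl)) next
    w <- 1 / censoring_km_left(survival$time, survival$event, survival$time[case])
    cmp <- outer(s[case], s[ctrl], function(a, b) (a > b) + 0.5 * (a == b))
    out$auc[i] <- sum(w * rowSums(cmp)) / (sum(w) * sum(ctrl))
  }
  class(out) <- c("timed_auc", "data.frame")
  out
}

score_vector <- function(scores, sample_ids) {
  if (is.data.frame(scores)) {
    s <- stats::setNames(scores$score, scores$sample_id)
  } else if (!is.null(names(scores))) {
    s <- scores
  } else {
    if (length(scores) != length(sample_ids)) stopf("scores do not match samples")
    return(as.numeric(scores))
  }
  miss <- setdiff(sample_ids, names(s))
  if (length(miss)) stopf("score missing for sample(s): %s",
                          paste(utils::head(miss, 5L), collapse = ", "))
  as.numeric(s[sample_ids])
}

#' Compare the time-dependent AUC of two scores by paired bootstrap
#'
#' Patients are resampled with replacement `n_boot` times; both scores'
#' IPCW AUCs are recomputed on each resample and a two-sided p-value for
#' `AUC_A(t) - AUC_B(t)` is read off the bootstrap distribution of the
#' difference.
#'
#' @param scoresA,scoresB Two scores over the same samples (score tables
#'   or named vectors).
#' @param survival A [survival_table()].
#' @param times Evaluation times.
#' @param n_boot Bootstrap replicates (default 500; below 100 a warning).
#' @param seed RNG seed.
#' @return A data.frame: `time`, `auc_a`, `auc_b`, `diff`, `p`.
#' @export
compare_auc <- function(scoresA, scoresB, survival, times, n_boot = 500L,
                        seed = 1L) {
  if (n_boot < 100L) warnf("n_boot < 100 gives unstable bootstrap p-values")
  sA <- score_vector(scoresA, survival$sample_id)
  sB <- score_vector(scoresB, survival$sample_id)
  obsA <- time_dependent_auc(sA, survival, times)$auc
  obsB <- time_dependent_auc(sB, survival, times)$auc
  n <- nrow(survival)
  boot <- with_seed(seed, {
    replicate(n_boot, {
      idx <- sample.int(n, replace = TRUE)
      sv <- survival[idx, , drop = FALSE]
      sv$sample_id <- sprintf("b%06d", seq_len(n))
      class(sv) <- class(survival)
      time_dependent_auc(sA[idx], sv, times)$auc -
        time_dependent_auc(sB[idx], sv, times)$auc
    })
  })
  boot <- matrix(boot, nrow = length(times))
  p <- vapply(seq_along(times), function(i) {
    d <- boot[i, ]
    d <- d[is.finite(d)]
    if (length(d) == 0L) return(NA_real_)
    min(1, 2 * min(mean(d <= 0), mean(d >= 0)))
  }, 0)
  data.frame(time = times, auc_a = obsA, auc_b = obsB, diff = obsA - obsB, p = p)
}
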