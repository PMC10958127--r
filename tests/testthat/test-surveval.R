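test_that("Kaplan-Meier estimates match hand-computed products", {
  sv <- survival_table(c("a", "b"), c(5, 9), c(1, 0))
  km <- kaplan_meier(sv)
  expect_equal(km$surv[km$time == 5], 0.5)
  expect_equal(min(km$surv), 0.5)  # the censored subject never drops the curve

  # classic 6-subject toy: deaths at 1 and 3, censoring at 2, 4, 5, 6
  sv6 <- survival_table(paste0("p", 1:6), c(1, 2, 3, 4, 5, 6),
                        c(1, 0, 1, 0, 0, 0))
  km6 <- kaplan_meier(sv6)
  expect_equal(km6$surv, km_by_hand(sv6$time, sv6$event, km6$time),
               tolerance = 1e-12)

  svc <- survival_table(paste0("p", 1:4), 1:4, rep(0, 4))
  expect_true(all(kaplan_meier(svc)$surv == 1))  # all censored

  # scaling time rescales the axis, not the probabilities
  km_scaled <- kaplan_meier(survival_table(paste0("p", 1:6), sv6$time * 7,
                                           sv6$event))
  expect_equal(km_scaled$time, km6$time * 7)
  expect_equal(km_scaled$surv, km6$surv)
})

test_that("the log-rank statistic matches an independent O/E/V tabulation", {
  # identical survival experience in both groups
  sv_dup <- survival_table(paste0("p", 1:8), rep(c(2, 5, 7, 9), 2),
                           rep(c(1, 1, 0, 1), 2))
  g_dup <- rep(c("x", "y"), each = 4)
  lr0 <- logrank_test(sv_dup, g_dup)
  expect_equal(lr0$chi2, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # 10-subject toy against brute-force accumulation over event times
  set.seed(11)
  time <- c(3, 5, 6, 8, 10, 2, 4, 7, 9, 12)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  grp <- rep(c("A", "B"), each = 5)
  sv <- survival_table(paste0("p", 1:10), time, event)
  lr <- logrank_test(sv, grp)
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == "A")
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == "A")
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$chi2, o_minus_e^2 / v, tolerance = 1e-10)

  # symmetry in group labeling
  lr_swap <- logrank_test(sv, ifelse(grp == "A", "B", "A"))
  expect_equal(lr_swap$chi2, lr$chi2)

  expect_error(logrank_test(sv, rep("A", 10)), "2 non-empty groups")
})

test_that("multivariate Cox matches a brute-force partial-likelihood maximizer", {
  # single binary covariate, no ties
  sv <- survival_table(paste0("p", 1:8),
                       c(1.5, 2.3, 3.1, 4.7, 5.2, 6.8, 7.4, 9.9),
                       c(1, 1, 0, 1, 1, 0, 1, 1),
                       x = c(1, 0, 1, 0, 1, 0, 0, 1))
  res <- cox_multivariate(sv, "x")
  # grid maximization of the (tie-free) Cox partial log-likelihood
  pll <- function(beta) {
    ll <- 0
    for (i in which(sv$event == 1)) {
      risk <- sv$time >= sv$time[i]
      ll <- ll + beta * sv$x[i] - log(sum(exp(beta * sv$x[risk])))
    }
    ll
  }
  beta_hat <- stats::optimize(pll, c(-4, 4), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(res$beta, beta_hat, tolerance = 1e-4)
  expect_equal(res$hr, exp(res$beta))
  expect_true(res$ci_low <= res$hr && res$hr <= res$ci_high)

  svd <- sv; svd$x2 <- svd$x
  expect_error(cox_multivariate(svd, c("x", "x2")), "rank-deficient")
  svc <- sv; svc$x <- 1
  expect_error(cox_multivariate(svc, "x"), "constant")
})

test_that("Cox hazard ratios are near 1 for null covariates", {
  ok <- 0L
  for (s in 1:50) {
    f <- simulate_fraction_matrix(500, c("A", "B"), seed = 300 + s)
    sv <- simulate_survival_from_fractions(f, c(A = 1), censor_rate = 0.2,
                                           seed = 400 + s)
    sv$noise <- with_seed_val(500 + s, rnorm(500))
    res <- cox_multivariate(sv, "noise")
    if (res$hr >= 0.85 && res$hr <= 1.18) ok <- ok + 1L
  }
  expect_gte(ok, 45L)
})

test_that("categorical covariates expand against the declared reference levels", {
  set.seed(6)
  n <- 120
  sv <- survival_table(sprintf("p%03d", 1:n), rexp(n, 0.01), rbinom(n, 1, 0.7),
                       sex = sample(c("Female", "Male"), n, TRUE),
                       cytogenetic_risk = sample(c("Favorable", "Intermediate", "Poor"),
                                                 n, TRUE),
                       age = runif(n, 20, 80))
  res <- cox_multivariate(sv, c("age", "sex", "cytogenetic_risk"))
  expect_true(any(grepl("sexMale", res$term)))
  expect_true(any(grepl("cytogenetic_riskIntermediate", res$term)))
  expect_true(any(grepl("cytogenetic_riskPoor", res$term)))
  expect_false(any(grepl("Female|riskFavorable", res$term)))
})

test_that("penalized (lambda = 0) and unpenalized Cox agree on shared toys", {
  toy <- toy_survival(n = 60, seed = 71, beta = c(1, -0.5), censor = 0.15)
  co_pen <- fit_lasso_cox(toy$X, toy$survival, lambda = 0)
  sv <- toy$survival
  sv$f1 <- toy$X[, 1]; sv$f2 <- toy$X[, 2]
  # Breslow vs Efron differ only at tied event times; these times are continuous
  co_un <- cox_multivariate(sv, c("f1", "f2"))
  expect_equal(unname(co_pen), co_un$beta, tolerance = 1e-4)
})

test_that("time-dependent AUC reduces to Mann-Whitney without censoring", {
  # perfect ranking: score reverses event-time order
  n <- 40
  sv <- survival_table(sprintf("p%02d", 1:n), seq_len(n), rep(1, n))
  perfect <- stats::setNames(rev(seq_len(n)), sv$sample_id)
  auc <- time_dependent_auc(perfect, sv, times = c(10, 20, 30))
  expect_true(all(auc$auc == 1))

  # uncensored 6-subject toy equals the hand-computed Mann-Whitney proportion
  sv6 <- survival_table(paste0("p", 1:6), c(2, 4, 5, 7, 8, 9), rep(1, 6))
  score6 <- stats::setNames(c(5, 6, 1, 3, 2, 4), sv6$sample_id)
  for (t in c(4.5, 7.5)) {
    cases <- sv6$time <= t
    mw <- mean(outer(score6[cases], score6[!cases], ">") +
                 0.5 * outer(score6[cases], score6[!cases], "=="))
    expect_equal(time_dependent_auc(score6, sv6, t)$auc, mw)
  }

  # no cases (or controls) at t: AUC missing
  expect_true(is.na(time_dependent_auc(score6, sv6, 1)$auc))
  expect_true(is.na(time_dependent_auc(score6, sv6, 100)$auc))
})

test_that("random scores give chance-level AUC and the true risk dominates noised versions", {
  f <- simulate_fraction_matrix(1000, LETTERS[1:5], seed = 13)
  beta <- c(A = 3, B = -2)
  sv <- simulate_survival_from_fractions(f, beta, censor_rate = 0.25, seed = 13)
  eta <- drop(f[, names(beta)] %*% beta)
  ts <- stats::quantile(sv$time, c(0.25, 0.5, 0.75))

  rnd <- with_seed_val(99, rnorm(1000))
  auc_rnd <- time_dependent_auc(stats::setNames(rnd, sv$sample_id), sv, ts)
  expect_true(all(auc_rnd$auc > 0.45 & auc_rnd$auc < 0.55))

  auc_true <- time_dependent_auc(stats::setNames(eta, sv$sample_id), sv, ts)
  noised <- eta + with_seed_val(100, rnorm(1000, sd = 2 * sd(eta)))
  auc_noised <- time_dependent_auc(stats::setNames(noised, sv$sample_id), sv, ts)
  expect_true(all(auc_true$auc > auc_noised$auc))
  expect_true(all(auc_true$auc > 0.5))
})

test_that("paired bootstrap AUC comparison is calibrated at the extremes and seeded", {
  f <- simulate_fraction_matrix(300, LETTERS[1:3], seed = 21)
  sv <- simulate_survival_from_fractions(f, c(A = 3), censor_rate = 0.2, seed = 21)
  eta <- stats::setNames(3 * f[, "A"], sv$sample_id)
  ts <- stats::quantile(sv$time, c(0.4, 0.6))

  same <- compare_auc(eta, eta, sv, ts, n_boot = 150, seed = 2)
  expect_true(all(same$diff == 0))
  expect_true(all(same$p == 1))

  rnd <- stats::setNames(with_seed_val(3, rnorm(300)), sv$sample_id)
  diffp <- compare_auc(eta, rnd, sv, ts, n_boot = 300, seed = 2)
  expect_true(all(diffp$p < 0.01))
  again <- compare_auc(eta, rnd, sv, ts, n_boot = 300, seed = 2)
  expect_identical(diffp, again)
  expect_warning(compare_auc(eta, rnd, sv, ts, n_boot = 50, seed = 1), "n_boot")
})
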