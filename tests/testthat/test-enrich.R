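toy_expr <- function() {
  m <- matrix(c(5.1, 2.0, 7.3, 1.2,
                3.3, 8.1, 2.2, 6.4,
                6.0, 6.2, 5.9, 6.1,
                1.0, 4.5, 9.0, 2.2,
                8.8, 3.1, 4.4, 7.7),
              nrow = 5, byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expression_matrix(m, scale = "log2")
}

test_that("enrichment scores match a hand-executed random walk on a 5x4 toy", {
  expr <- toy_expr()
  sets <- gene_set_collection(list(up = c("g1", "g5"), mixed = c("g2", "g3", "g4")))
  for (mode in c("max_diff", "max_dev")) {
    es <- gsva_scores(expr, sets, mode = mode)
    expect_equal(unname(es["up", ]),
                 es_by_hand(unclass(expr), c("g1", "g5"), mode = mode))
    expect_equal(unname(es["mixed", ]),
                 es_by_hand(unclass(expr), c("g2", "g3", "g4"), mode = mode))
  }
  # tau reweighting changes the walk as the oracle says
  es2 <- gsva_scores(expr, sets, tau = 0.5)
  expect_equal(unname(es2["up", ]),
               es_by_hand(unclass(expr), c("g1", "g5"), tau = 0.5))
})

test_that("enrichment scores are invariant to affine per-gene rescaling and sample order", {
  expr <- toy_expr()
  sets <- gene_set_collection(list(up = c("g1", "g5")))
  base <- gsva_scores(expr, sets)
  m2 <- unclass(expr) * 3.7 + 11  # affine transform leaves kernel-CDF ranks intact
  expect_equal(unname(gsva_scores(expression_matrix(m2, "log2"), sets)),
               unname(base), tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  es_perm <- gsva_scores(expression_matrix(unclass(expr)[, perm], "log2"), sets)
  expect_equal(es_perm[, colnames(base)], base, ignore_attr = TRUE)
})

test_that("sets without valid genes are skipped, not scored", {
  expr <- toy_expr()
  sets <- gene_set_collection(list(ok = c("g1", "g2"), ghost = c("zz1", "zz2")))
  es <- gsva_scores(expr, sets)
  expect_equal(rownames(es), "ok")
  expect_equal(attr(es, "skipped_sets"), "ghost")
  expect_equal(attr(es, "valid_genes"), c(ok = 2L))
})

test_that("a planted overexpression block maximizes that sample's enrichment", {
  des <- tiny_design(k = 2, g = 300, markers = 10, noise_sd = 0.4, seed = 91)
  r <- simulate_reference_profiles(des)
  target <- colnames(r$profiles)[1]
  set_genes <- rownames(r$profiles)[101:130]
  shifted <- plant_gene_set_signal(r$profiles, target, set_genes, 4)
  es <- gsva_scores(shifted, gene_set_collection(list(planted = set_genes)))
  expect_equal(names(which.max(es["planted", ])), target)
})

test_that("PAM clustering separates distinct enrichment profiles and honors its contract", {
  set.seed(17)
  blob <- cbind(matrix(rnorm(6 * 20, mean = 0, sd = 0.5), nrow = 6),
                matrix(rnorm(6 * 20, mean = 5, sd = 0.5), nrow = 6))
  dimnames(blob) <- list(paste0("set", 1:6), sprintf("s%02d", 1:40))
  cl <- pam_cluster(blob, k = 2)
  expect_true(all(cl$medoids %in% colnames(blob)))
  expect_length(unique(cl$labels[1:20]), 1L)
  expect_length(unique(cl$labels[21:40]), 1L)
  expect_false(cl$labels[1] == cl$labels[40])

  # duplicating every sample leaves the medoid profiles unchanged
  dup <- cbind(blob, blob)
  colnames(dup) <- c(colnames(blob), paste0(colnames(blob), "_dup"))
  cl_dup <- pam_cluster(dup, k = 2)
  med1 <- blob[, sub("_dup$", "", cl_dup$medoids)]
  med0 <- blob[, cl$medoids]
  expect_equal(unname(med1[, order(med1[1, ])]), unname(med0[, order(med0[1, ])]))

  # the PAM objective is no worse than random medoid choices
  d <- as.matrix(dist(t(blob)))
  set.seed(5)
  for (rep in 1:20) {
    meds <- sample(colnames(blob), 2)
    rnd_cost <- sum(apply(d[, meds], 1, min))
    expect_lte(cl$objective, rnd_cost + 1e-9)
  }

  expect_error(pam_cluster(blob, k = 0), "positive")
  expect_error(pam_cluster(blob, k = 40), "smaller")
})


test_that("Fisher concordance matches full hypergeometric enumeration", {
  a <- rep(c(0, 1), times = c(10, 10))
  res <- fisher_concordance(a, a)
  expect_equal(res$p, fisher_p_enum(matrix(c(10, 0, 0, 10), 2)))
  expect_true(is.infinite(res$odds_ratio))  # perfect concordance

  set.seed(23)
  for (rep in 1:20) {
    n <- sample(8:30, 1)
    x <- rbinom(n, 1, 0.5); y <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(fisher_concordance(x, y)$p, fisher_p_enum(table(x, y)),
                 tolerance = 1e-10)
  }

  expect_warning(res0 <- fisher_concordance(rep(1, 10), rbinom(10, 1, 0.5)),
                 "degenerate")
  expect_equal(res0$p, 1)
})

test_that("score/gene-set correlation matrices behave at the extremes", {
  set.seed(31)
  es <- matrix(rnorm(3 * 60), nrow = 3,
               dimnames = list(c("up", "down", "noise"), sprintf("s%02d", 1:60)))
  es["down", ] <- -es["up", ]
  scores <- list(lsca_like = stats::setNames(es["up", ], colnames(es)))
  res <- score_geneset_correlations(es, scores)
  expect_equal(diag(res$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(res$r["up", "down"], -1)
  expect_equal(res$r["up", "lsca_like"], 1)
  expect_true(res$adj_p["up", "down"] < 0.001)
  expect_equal(res$stars["up", "lsca_like"], "***")
  expect_equal(res$adj_p, t(res$adj_p))

  # zero-variance rows report missing correlations
  es0 <- rbind(es, flat = rep(1, 60))
  res0 <- score_geneset_correlations(es0, scores)
  expect_true(all(is.na(res0$r["flat", ])))
})

test_that("independent rows rarely show large spurious correlation", {
  hits <- 0L
  set.seed(41)
  for (rep in 1:100) {
    x <- rnorm(500); y <- rnorm(500)
    if (abs(cor(x, y)) < 0.15) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("group-wise enrichment differences detect planted shifts and flag skipped sets", {
  set.seed(51)
  n_per <- 30
  es <- matrix(rnorm(4 * 2 * n_per, sd = 0.5), nrow = 4,
               dimnames = list(paste0("set", 1:4),
                               sprintf("s%02d", 1:(2 * n_per))))
  groups <- stats::setNames(rep(c("high", "low"), each = n_per), colnames(es))
  # identical groups: zero effect
  es_same <- es; es_same[, 1:n_per] <- es[, (n_per + 1):(2 * n_per)]
  d0 <- groupwise_es_difference(es_same, groups)
  expect_equal(d0$es_diff, rep(0, 4))

  es_shift <- es
  es_shift["set1", 1:n_per] <- es_shift["set1", 1:n_per] + 1
  es_shift["set2", 1:n_per] <- es_shift["set2", 1:n_per] - 1
  attr(es_shift, "skipped_sets") <- "ghost_set"
  d <- groupwise_es_difference(es_shift, groups)
  expect_gt(d$es_diff[d$set == "set1"], 0)
  expect_lt(d$es_diff[d$set == "set2"], 0)
  expect_lt(d$adj_p[d$set == "set1"], 0.05)
  expect_lt(d$adj_p[d$set == "set2"], 0.05)
  ghost <- d[d$set == "ghost_set", ]
  expect_true(ghost$skipped)
  expect_true(is.na(ghost$es_diff))

  expect_error(groupwise_es_difference(es, rep("high", 2 * n_per)), "non-empty")
})
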