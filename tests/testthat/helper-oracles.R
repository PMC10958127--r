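# Independent oracles used by both module and acceptance tests.

# Step-by-step single-sample enrichment oracle: explicit loops, no shared
# code with the package implementation.
es_by_hand <- function(m, set, tau = 1, mode = "max_diff") {
  p <- nrow(m); n <- ncol(m)
  z <- matrix(NA_real_, p, n)
  for (i in 1:p) {
    h <- sd(m[i, ]) / 4
    for (j in 1:n) {
      acc <- 0
      for (k in 1:n) acc <- acc + pnorm((m[i, j] - m[i, k]) / h)
      z[i, j] <- acc / n
    }
  }
  out <- numeric(n)
  for (j in 1:n) {
    ord <- order(z[, j], decreasing = TRUE)
    walk <- 0; vmax <- 0; vmin <- 0; vbest <- 0
    wsum <- 0
    for (pos in 1:p) if (rownames(m)[ord[pos]] %in% set) {
      wsum <- wsum + abs(pos - p / 2)^tau
    }
    mset <- sum(rownames(m) %in% set)
    for (pos in 1:p) {
      g <- rownames(m)[ord[pos]]
      if (g %in% set) walk <- walk + abs(pos - p / 2)^tau / wsum
      else walk <- walk - 1 / (p - mset)
      if (walk > vmax) vmax <- walk
      if (walk < vmin) vmin <- walk
      if (abs(walk) > abs(vbest)) vbest <- walk
    }
    out[j] <- if (mode == "max_diff") vmax + vmin else vbest
  }
  out
}

# Two-sided Fisher p by full hypergeometric enumeration (R convention:
# total probability of tables no more likely than the observed one).
fisher_p_enum <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(a_range, c1, n - c1, r1)
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
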