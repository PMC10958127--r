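# Shared fixtures, built in code at test time.

# Tiny labeled reference panel: `k` cell types, `g` genes, `markers` planted
# markers per type.
tiny_design <- function(k = 3L, g = 120L, markers = 10L, noise_sd = 0.2,
                        reps = 4L, seed = 42L, n_mixtures = 30L) {
  synthetic_design(n_genes = g, cell_types = LETTERS[seq_len(k)],
                   markers_per_type = markers, marker_log2fc = 2,
                   replicates_per_type = reps, noise_sd = noise_sd,
                   n_mixtures = n_mixtures, seed = seed)
}

# A small survival data set with continuous (tie-free) times and
# independent uniform features.
toy_survival <- function(n = 50L, seed = 1L, beta = c(1.5, 0), censor = 0.2) {
  X <- with_seed_val(seed, matrix(runif(n * length(beta)), nrow = n,
                                  dimnames = list(sprintf("P%03d", seq_len(n)),
                                                  paste0("f", seq_along(beta)))))
  sv <- simulate_survival_from_fractions(
    X, stats::setNames(beta, colnames(X)),
    baseline_scale = 100, censor_rate = censor, seed = seed)
  list(X = X, survival = sv)
}

# Evaluate an expression under a fixed seed (test-local convenience).
with_seed_val <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Independent straight-line Kaplan-Meier product for oracle checks.
km_by_hand <- function(time, event, at) {
  ts <- sort(unique(time[event == 1]))
  vapply(at, function(t) {
    s <- 1
    for (ti in ts[ts <= t]) {
      n_i <- sum(time >= ti)
      d_i <- sum(time == ti & event == 1)
      s <- s * (1 - d_i / n_i)
    }
    s
  }, 0)
}
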