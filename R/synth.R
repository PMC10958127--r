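# Synthetic-data generators. These produce every input the pipeline needs:
# cell-type-sorted reference profiles with planted marker blocks, Dirichlet
# mixing fractions, pseudo-bulk cohorts mixed in linear expression space,
# survival outcomes driven by a proportional-hazards model on the true
# fractions, and gene sets with planted group-wise shifts. Every generator
# is a pure function of its design and seed.

#' Describe a synthetic study design
#'
#' Defaults emulate a cell-type-sorted reference panel for the nine
#' HemLin9 populations: 50 disjoint marker genes per type elevated by
#' 2 log2 units over a shared baseline, 4 sorted replicates per type, and
#' uniform-on-the-simplex (Dirichlet alpha = 1) mixing fractions for 100
#' pseudo-bulk samples.
#'
#' @param n_genes Total number of genes.
#' @param cell_types Character vector of cell-type names.
#' @param markers_per_type Planted marker genes per type (disjoint blocks).
#' @param marker_log2fc Elevation of a type's markers over baseline (log2).
#' @param replicates_per_type Sorted replicate samples per type.
#' @param noise_sd Gaussian noise SD on log2 expression.
#' @param dirichlet_alpha Dirichlet concentration (scalar or per-type vector).
#' @param n_mixtures Number of pseudo-bulk samples.
#' @param seed Master RNG seed.
#' @return A list of class `"synthetic_design"`.
#' @export
synthetic_design <- function(n_genes = 2000L,
                             cell_types = hemlin9_cell_types(),
                             markers_per_type = 50L,
                             marker_log2fc = 2,
                             replicates_per_type = 4L,
                             noise_sd = 0.25,
                             dirichlet_alpha = 1,
                             n_mixtures = 100L,
                             seed = 1L) {
  d <- list(n_genes = as.integer(n_genes), cell_types = as.character(cell_types),
            markers_per_type = as.integer(markers_per_type),
            marker_log2fc = as.numeric(marker_log2fc),
            replicates_per_type = as.integer(replicates_per_type),
            noise_sd = as.numeric(noise_sd),
            dirichlet_alpha = as.numeric(dirichlet_alpha),
            n_mixtures = as.integer(n_mixtures), seed = as.integer(seed))
  if (d$n_genes < 1L || d$markers_per_type < 1L || d$replicates_per_type < 1L ||
      d$n_mixtures < 1L) stopf("all design counts must be >= 1")
  if (d$marker_log2fc < 0 || d$noise_sd < 0) stopf("effect and noise must be >= 0")
  if (any(d$dirichlet_alpha <= 0)) stopf("dirichlet_alpha must be positive")
  if (d$markers_per_type * length(d$cell_types) > d$n_genes) {
    stopf("marker blocks would overlap: %d types x %d markers > %d genes",
          length(d$cell_types), d$markers_per_type, d$n_genes)
  }
  class(d) <- "synthetic_design"
  d
}

#' Simulate cell-type-sorted reference profiles
#'
#' Generates a log2-scale expression matrix with `replicates_per_type`
#' sorted samples per cell type. Each gene has a baseline log2 level drawn
#' once from U(3, 8); each type's disjoint marker block is elevated by
#' `marker_log2fc`; i.i.d. Gaussian noise with SD `noise_sd` is added.
#' The planted marker assignment is recorded in the `marker_genes`
#' attribute (a named list per type).
#'
#' @param design A [synthetic_design()].
#' @return List with `profiles` (log2 [expression_matrix()]) and `labels`
#'   (a [cell_type_labels()] vector).
#' @export
simulate_reference_profiles <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  K <- length(design$cell_types)
  n_samp <- K * design$replicates_per_type
  genes <- sprintf("G%05d", seq_len(design$n_genes))
  samples <- paste0(rep(design$cell_types, each = design$replicates_per_type),
                    "_rep", rep(seq_len(design$replicates_per_type), K))
  labels <- cell_type_labels(samples,
                             rep(design$cell_types, each = design$replicates_per_type))
  marker_idx <- split(seq_len(design$markers_per_type * K),
                      rep(seq_len(K), each = design$markers_per_type))
  names(marker_idx) <- design$cell_types
  vals <- with_seed(derive_seed(design$seed, 1L), {
    base <- stats::runif(design$n_genes, 3, 8)
    m <- matrix(base, nrow = design$n_genes, ncol = n_samp)
    for (k in seq_len(K)) {
      cols <- which(labels == design$cell_types[k])
      m[marker_idx[[k]], cols] <- m[marker_idx[[k]], cols] + design$marker_log2fc
    }
    m + matrix(stats::rnorm(design$n_genes * n_samp, sd = design$noise_sd),
               nrow = design$n_genes)
  })
  dimnames(vals) <- list(genes, samples)
  profiles <- expression_matrix(vals, scale = "log2")
  attr(profiles, "marker_genes") <- lapply(marker_idx, function(i) genes[i])
  list(profiles = profiles, labels = labels)
}

#' Simulate a Dirichlet fraction matrix
#'
#' Rows are drawn i.i.d. from Dirichlet(alpha) over the given cell types,
#' so each sample's fractions are non-negative and sum to one.
#'
#' @param n_samples Number of samples (rows).
#' @param cell_types Cell-type names (columns).
#' @param alpha Concentration parameter, scalar or per-type vector.
#' @param seed RNG seed.
#' @return Numeric samples x types matrix with rownames `S0001`, ...
#' @export
simulate_fraction_matrix <- function(n_samples, cell_types = hemlin9_cell_types(),
                                     alpha = 1, seed = 1L) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stopf("n_samples must be >= 1")
  K <- length(cell_types)
  alpha <- rep_len(as.numeric(alpha), K)
  if (any(alpha <= 0)) stopf("Dirichlet alpha must be positive")
  g <- with_seed(seed, matrix(stats::rgamma(n_samples * K,
                                            shape = rep(alpha, each = n_samples)),
                              nrow = n_samples))
  f <- g / rowSums(g)
  dimnames(f) <- list(sprintf("S%04d", seq_len(n_samples)), cell_types)
  f
}

#' Build pseudo-bulk mixtures from sorted profiles
#'
#' Computes per-gene, per-cell-type medians across the sorted replicates
#' and sums the fraction-weighted medians across cell types for each
#' sample: output = M %*% t(F) with M the genes x types median matrix and
#' F the samples x types fraction matrix. Mixing happens in linear
#' expression units; log2 profiles are exponentiated first.
#'
#' @param profiles Reference [expression_matrix()] (any scale).
#' @param labels [cell_type_labels()] for the profile columns.
#' @param fractions Samples x types fraction matrix.
#' @return Linear-scale [expression_matrix()], genes x samples.
#' @export
make_pseudobulk <- function(profiles, labels, fractions) {
  validate_labels(labels, profiles, min_reps = 1L)
  missing_types <- setdiff(colnames(fractions), unique(labels))
  if (length(missing_types)) {
    stopf("fraction cell type(s) absent from labels: %s",
          paste(missing_types, collapse = ", "))
  }
  M <- celltype_median_profiles(profiles, labels)[, colnames(fractions), drop = FALSE]
  out <- M %*% t(fractions)
  colnames(out) <- rownames(fractions)
  expression_matrix(out, scale = "linear")
}

# genes x types matrix of per-type median linear expression.
celltype_median_profiles <- function(profiles, labels) {
  lin <- to_linear(profiles)
  types <- unique(labels)
  M <- vapply(types, function(t) {
    cols <- names(labels)[labels == t]
    sub <- unclass_expr(lin)[, cols, drop = FALSE]
    apply(sub, 1L, stats::median)
  }, numeric(nrow(lin)))
  rownames(M) <- rownames(lin)
  M
}

#' Simulate survival outcomes from cell-type fractions
#'
#' Event times follow an exponential proportional-hazards model with
#' linear predictor `eta = sum_c beta_c * F_c`: `T = rexp(rate =
#' exp(eta) / baseline_scale)`. Independent uniform censoring on `[0, c]`
#' is applied, with `c` solved numerically so the expected censored
#' proportion matches `censor_rate`.
#'
#' @param fractions Samples x types fraction matrix.
#' @param coefficients Named numeric vector of true log-hazard coefficients
#'   (names must be fraction columns).
#' @param baseline_scale Baseline mean survival time at eta = 0.
#' @param censor_rate Target expected proportion censored, in `[0, 1)`.
#' @param seed RNG seed.
#' @return A [survival_table()] with attribute `truth` recording the
#'   generating coefficients, baseline scale and censoring bound.
#' @export
simulate_survival_from_fractions <- function(fractions, coefficients,
                                             baseline_scale = 365,
                                             censor_rate = 0.3, seed = 1L) {
  if (length(coefficients) == 0L) stopf("coefficient vector must be non-empty")
  miss <- setdiff(names(coefficients), colnames(fractions))
  if (length(miss)) stopf("coefficient(s) for unknown fraction column: %s",
                          paste(miss, collapse = ", "))
  if (censor_rate < 0 || censor_rate >= 1) stopf("censor_rate must be in [0, 1)")
  eta <- drop(fractions[, names(coefficients), drop = FALSE] %*% coefficients)
  n <- nrow(fractions)
  res <- with_seed(seed, {
    t_event <- stats::rexp(n, rate = exp(eta) / baseline_scale)
    if (censor_rate == 0) {
      list(time = t_event, event = rep(1, n), cmax = Inf)
    } else {
      # With C ~ U(0, c), P(censored | T = t) = min(t / c, 1); solve for c
      # matching the target rate on this draw of event times.
      f <- function(cc) mean(pmin(t_event / cc, 1)) - censor_rate
      hi <- max(t_event) * 2
      cmax <- if (f(hi) > 0) hi else stats::uniroot(f, c(min(t_event) * 1e-6, hi))$root
      cens <- stats::runif(n, 0, cmax)
      list(time = pmin(t_event, cens), event = as.numeric(t_event <= cens),
           cmax = cmax)
    }
  })
  out <- survival_table(rownames(fractions), res$time, res$event, time_unit = "days")
  attr(out, "truth") <- list(coefficients = coefficients,
                             baseline_scale = baseline_scale,
                             censor_bound = res$cmax)
  out
}

#' Plant a group-wise gene-set shift into a bulk matrix
#'
#' Shifts the expression of `gene_set` genes by `+delta` log2 units in the
#' samples of the designated group only (linear matrices are multiplied by
#' `2^delta`); everything else is untouched. Used to create ground truth
#' for enrichment-direction tests.
#'
#' @param bulk An [expression_matrix()].
#' @param group_samples Character vector of sample ids receiving the shift.
#' @param gene_set Character vector of genes to shift (must exist in bulk).
#' @param delta Log2-scale shift (may be negative).
#' @return The modified [expression_matrix()].
#' @export
plant_gene_set_signal <- function(bulk, group_samples, gene_set, delta) {
  unknown <- setdiff(gene_set, rownames(bulk))
  if (length(unknown)) stopf("unknown gene(s): %s",
                             paste(utils::head(unknown, 5L), collapse = ", "))
  unknown_s <- setdiff(group_samples, colnames(bulk))
  if (length(unknown_s)) stopf("unknown sample(s): %s",
                               paste(utils::head(unknown_s, 5L), collapse = ", "))
  if (delta == 0) return(bulk)
  sc <- expr_scale(bulk)
  m <- unclass_expr(bulk)
  if (sc == "log2") {
    m[gene_set, group_samples] <- m[gene_set, group_samples] + delta
  } else {
    m[gene_set, group_samples] <- m[gene_set, group_samples] * 2 ^ delta
  }
  expression_matrix(m, scale = sc)
}

#' Simulate a complete synthetic AML cohort
#'
#' Convenience wrapper chaining the generators: sorted reference profiles,
#' Dirichlet mixing fractions, a linear-scale pseudo-bulk matrix, and
#' survival outcomes driven by the true fractions.
#'
#' @param design A [synthetic_design()].
#' @param coefficients Named true log-hazard coefficients over cell types.
#' @param baseline_scale,censor_rate Passed to
#'   [simulate_survival_from_fractions()].
#' @return List of class `"synthetic_cohort"` with elements `profiles`,
#'   `labels`, `bulk`, `true_fractions`, `survival` and `truth`.
#' @export
simulate_cohort <- function(design = synthetic_design(),
                            coefficients = c(GMP = -2.15, CMP = -1.64,
                                             RApos = 0.37, MEP = 0.49,
                                             MPP = 4.52),
                            baseline_scale = 365, censor_rate = 0.3) {
  ref <- simulate_reference_profiles(design)
  fr <- simulate_fraction_matrix(design$n_mixtures, design$cell_types,
                                 alpha = design$dirichlet_alpha,
                                 seed = derive_seed(design$seed, 2L))
  bulk <- make_pseudobulk(ref$profiles, ref$labels, fr)
  surv <- simulate_survival_from_fractions(fr, coefficients, baseline_scale,
                                           censor_rate,
                                           seed = derive_seed(design$seed, 3L))
  structure(list(profiles = ref$profiles, labels = ref$labels, bulk = bulk,
                 true_fractions = fr, survival = surv,
                 truth = attr(surv, "truth")),
            class = "synthetic_cohort")
}
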