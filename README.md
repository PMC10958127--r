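# lsca

Cell-type abundance deconvolution and the **LSCA** (leukemic stem cell
activity) prognostic score for acute myeloid leukemia (AML).

## The problem

Bulk AML transcriptomes mix malignant blasts with normal hematopoietic
stem and progenitor populations. The relative abundance of those
populations carries prognostic information, but it is latent in bulk
data. This package implements the full pipeline that turns bulk
expression into a survival score based only on deconvoluted cell-type
composition:

1. **Signature construction** — one-vs-rest differential expression on
   cell-type-sorted reference profiles (moderated t, log2FC >= 1,
   BH-adjusted p thresholds with per-type overrides, top-N capping)
   yields a marker-gene x cell-type matrix of median linear-scale
   expression over nine hematopoietic populations (AML blasts, CMP, GMP,
   HSC, LPC, LSC, MEP, MPP, and CD45RA+ cells).
2. **Deconvolution** — per-sample mixture regression of bulk expression
   on the signature estimates a fraction vector `F` on the simplex,
   either by CIBERSORT-style linear nu-SVR (nu in {0.25, 0.5, 0.75},
   chosen by reconstruction RMSE) or by non-negative least squares.
3. **Score derivation** — stability-selected LASSO Cox regression of
   overall survival on the fractions: cross-validated `cv.glmnet` fits
   are repeated (100 iterations by default), cell types whose
   coefficient is shrunk to exactly zero in more than `zero_limit`
   iterations are filtered out, and each survivor's coefficient is the
   mean over all iterations. The published model is

   `LSCA = -2.15 F_GMP - 1.64 F_CMP + 0.37 F_RApos + 0.49 F_MEP + 4.52 F_MPP`

   and ships as `lsca_paper_model()`.
4. **Validation** — Kaplan-Meier curves, log-rank tests, multivariate
   Cox regression (age, sex, cytogenetic risk, score), IPCW
   time-dependent AUC with a paired bootstrap comparison test, and
   GSVA-style single-sample enrichment of LSC-related gene sets with
   k-medoids (PAM) clustering, Fisher's exact concordance, and
   group-wise enrichment differences.

A synthetic-data module generates every input the pipeline needs
(sorted reference profiles with planted markers, Dirichlet mixing
fractions, pseudo-bulk cohorts mixed in linear space, survival outcomes
driven by a proportional-hazards model on the true fractions, gene sets
with planted shifts), so the whole pipeline is testable without any
cohort download.

## Worked example

```r
library(lsca)

design <- synthetic_design(n_genes = 1200, markers_per_type = 30,
                           replicates_per_type = 4, noise_sd = 0.25,
                           n_mixtures = 120, seed = 1)
cohort <- simulate_cohort(design, coefficients = c(GMP = -2.15, CMP = -1.64,
                                                   RApos = 0.37, MEP = 0.49,
                                                   MPP = 4.52))

degs      <- differential_expression_one_vs_rest(cohort$profiles, cohort$labels)
markers   <- select_marker_genes(degs, logfc_min = 1, adjp_default = 0.05, top_n = 30)
signature <- build_signature_matrix(cohort$profiles, cohort$labels, markers)
fractions <- deconvolve_nnls(signature, cohort$bulk)
evaluate_fraction_recovery(cohort$true_fractions, fractions, method = "NNLS")
#> fraction recovery report (NNLS)
#> per-cell-type Pearson correlation:
#> AML_blast       CMP       GMP       HSC       LPC       LSC       MEP       MPP
#>         1         1         1         1         1         1         1         1
#>     RApos
#>         1
#> median per-sample RMSE: 6.151e-17

model <- lsca(fractions, cohort$survival, n_iter = 25, n_folds = 10, seed = 1)
model
#> LSCA score model (fitted)
#> coefficients:
#>     CMP     MPP
#> -3.3890  5.5977
#> retained 2 of 9 cell types (zero_limit = 5, n_iter = 25)
#> dropped: AML_blast, GMP, HSC, LPC, LSC, MEP, RApos

scores <- predict(model, fractions)
groups <- split_by_threshold(scores, method = "median")
lr <- logrank_test(cohort$survival,
                   setNames(as.character(groups$group), groups$sample_id))
#> log-rank chi2 = 24.08, p = 9.25e-07
time_dependent_auc(scores, cohort$survival,
                   times = quantile(cohort$survival$time, c(0.25, 0.5, 0.75)))
#>       time       auc n_cases n_controls
#>   76.86558 0.7524526      26         90
#>  154.84854 0.7488096      51         60
#>  332.77799 0.7659491      73         30
```

The fractions of this 120-sample pseudo-bulk cohort are recovered
essentially exactly (the mixtures are noiseless weighted sums of the
same median profiles the signature is built from). The stability-
selected model keeps CMP (protective, negative coefficient) and MPP
(adverse, positive) — the two types whose true log-hazard weights have
the largest magnitudes relative to their fraction variability at this
cohort size — splits the cohort into clearly separated survival groups
(log-rank p ~ 1e-6), and ranks patients with time-dependent AUC around
0.75.

To score any cohort with the published coefficients instead of
refitting:

```r
scores <- predict(lsca_paper_model(), fractions)
```

## Documentation

The methods vignette (`vignettes/lsca-methods.Rmd`) describes the
statistical model behind every stage, the tunable parameters and their
defaults, what the synthetic generator does and does not emulate, and
the numerical conventions (tie-breaking, degenerate inputs, scale
handling).
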