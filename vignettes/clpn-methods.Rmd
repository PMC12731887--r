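---
title: "Cross-lagged panel networks for two-wave symptom data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-lagged panel networks for two-wave symptom data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clpnet)
```

## The estimation problem

Two psychological constructs are measured twice in the same subjects:
death anxiety (DA; four subscales D1 Cognition, D2 Emotion, D3 Time
awareness, D4 Stress and pain) and fear of cancer recurrence (FCR; seven
subscales F1 Triggers through F7 Coping strategies), at hospital discharge
(T1) and three months later (T2). A cross-lagged panel network (CLPN)
answers "which symptom at T1 predicts which symptom at T2, over and above
every other symptom?" by a chain of regularized regressions: for each of
the eleven T2 outcomes, an L1-penalized (LASSO) regression on all eleven
standardized T1 subscales plus demographic covariates. The resulting
11 x 11 coefficient matrix (predictors in rows) is a directed network:
diagonal entries are autoregressive paths, off-diagonal entries cross-lagged
paths. Edges are reported as odds ratios `OR = exp(coefficient)`, so an
absent (zero) edge prints as exactly 1. Unlike SEM-style cross-lagged
models there is no global fit index; inference rests on bootstrap stability
instead.

### Model family

The subscale scores are sums of Likert items, i.e. continuous-ish
non-negative variables, and the reference cohort reports continuous means
and SDs per wave. The default estimator is therefore a **Gaussian** LASSO
on standardized outcomes, so coefficients are standardized effects that
are comparable across nodes — a requirement for summing them into
centrality indices. Because the OR reporting transform originates in a
logistic reading of these models, a **binomial mode** is also provided
(`clpn_settings(family = "binomial")` after `dichotomize_wave2()`, which
median-splits the T2 scores); the exponentiation is applied to whatever
coefficient the chosen mode produces. No dichotomization rule is implied
by the data themselves, which is why the continuous mode is the default.

### Penalty selection and standardization

- Predictors are z-scored on the analysis sample; in Gaussian mode the
  outcome is z-scored too.
- The penalty applies only to the eleven lagged predictors. Covariates
  (age plus categorical education / marital status / occupation / income,
  expanded by `model.matrix`) enter unpenalized: they are confounder
  adjustments, not candidate edges.
- `lambda` is selected per node by 10-fold cross-validation at the CV
  minimum (`lambda_rule = "min"`), folds drawn from the settings seed so a
  fit is reproducible. The conservative `"1se"` rule is available; on pure
  noise it returns the exactly empty network, while CV-min typically
  retains a few spurious edges (roughly 3--25% of the 110 possible
  cross-lagged entries at n = 426 in our null replicates).
- Coefficients with magnitude below `zero_tol = 1e-9` are treated as
  structural zeros by the edge census and centrality code; this makes
  3-decimal fixture matrices (entries printed as 1.000) behave exactly.

## Centrality

Expected influence keeps the sign of every edge (it is not "strength"):
out-EI of node i is the signed sum of its outgoing cross-lagged edges,
in-EI of node j the signed sum of incoming ones, and the one-step bridge
variants restrict the sums to edges crossing the DA|FCR partition. The
autoregressive diagonal is always excluded.

Two weight scales are supported and always labeled: the coefficient
(log-OR) scale, natural for freshly estimated networks, and `OR - 1`,
natural for fixture matrices that store printed odds ratios. Rank orders
are stable across the two scales for all reference-network claims except
one: on the printed 3-decimal matrix the in-EI column sums are
F3 = 0.462, D1 = 0.421, F2 = 0.411 (OR-1 scale), so the top-two set
{F3, F2} reported for the original (unrounded) estimates is not
recoverable from the rounded table — D1 and F2 sit a rounding hair apart.
The package surfaces the scale rather than hiding it, and the test suite
documents this discrepancy explicitly.

Ties in ranked edges and block extrema break lexicographically by
(predictor, outcome) node order, for determinism.

## Resampling

`bootstrap_edges()` resamples subjects with replacement and re-estimates
the whole network per resample; per-edge 95% intervals are percentile
intervals (adequate for edge weights, and matching common usage; BCa is
out of scope). Difference tests for edges and centralities are percentile
tests on the bootstrap distribution of the difference, with self-comparisons
flagged trivially non-significant. Resample b draws its RNG substream from
a seed table generated once, so results do not depend on execution order.

`cs_coefficient()` implements the case-dropping subset bootstrap: for drop
proportions 0.05--0.75 (step 0.05) it correlates subsample centrality with
the full-sample centrality across the eleven nodes; CS is the largest
proportion at which at least 95% of correlations reach 0.7 (the
conventional constants; both configurable). Proportions whose subsample
would fall below 30 subjects are marked infeasible and excluded. A CS
above 0.25 is conventionally acceptable, above 0.50 robust.

**Penalty handling in resampling.** By default the penalty is re-selected
inside every resample/subsample (`refit_lambda = TRUE`) — honest
uncertainty about the full pipeline. A frozen-penalty mode reuses the
full-sample per-node penalties for speed. The choice matters most at small
n: freezing the penalty lets subsamples inherit the full sample's active
set, which inflates apparent stability on noise (we measured CS = 0.2
frozen vs 0 refit on a pure-noise cohort of 100 subjects). At n = 2000 the
selection is stable and the two modes agree. The test suite therefore uses
the frozen path for large-n stability checks and full re-selection for the
small-n noise check.

## Subgroup comparison

`split_by_stage()` pools stages I/II (early) versus III/IV (advanced);
`compare_networks()` fits both networks with a shared selection procedure
(the penalty value is re-selected per group — the groups differ in size,
and one fixed value would conflate sparsity with sample size) and reports
per-group centralities, per-block strongest edges, and the descriptive
difference matrix `coeff_early - coeff_advanced`. The comparison is
deliberately descriptive, mirroring how such contrasts are usually
reported; `permutation_comparison()` is an explicitly labeled inferential
extension that permutes subjects across group labels and tests the maximum
absolute cross-lagged difference and the cross-lagged global-strength
difference. Autoregressive paths are excluded from both statistics so that
they track the cross-lagged structure the comparison is about.

## The synthetic cohort generator

`clpn_sim_spec()` / `simulate_cohort()` emulate the reference cohort so the
whole pipeline is testable end to end without any raw data:

- **Wave 1**: multivariate normal with block-exchangeable correlation
  (0.4 within each construct, 0.2 between), rescaled to the published
  per-subscale means/SDs and truncated at zero (scores are non-negative
  item sums).
- **Wave 2**: standardized outcomes follow
  `z(T2_j) = auto_j z(T1_j) + sum_i cross[i,j] z(T1_i) + covariates + noise`,
  rescaled to the wave-2 means/SDs and truncated at zero. Default
  autoregressive coefficients are 0.45 throughout; the default cross-lagged
  matrix is sparse with strong positive paths D2->D1 (0.29), D3->D4 (0.20),
  D3->F3 (0.31), D1->F2/F4/F7 (0.24/0.26/0.23), D4->F1 (0.20), weak
  positive F2->F1 and F1->F6, and weak negative paths out of F7 —
  qualitatively the published edge pattern, with autoregressive paths
  dominating cross-lagged ones on average. Residual SDs default to the
  value that makes each standardized outcome's variance one.
- **Covariates**: age ~ normal(47.30, 11.27) truncated to [18, 90];
  categorical covariates multinomial with the cohort's observed
  proportions; covariate effects default to zero (the covariates are
  adjustment variables, so simulation-based tests may skip them for speed
  without changing the estimand).
- **Missingness**: each subject loses the entire second wave with
  probability 0.0467 (MCAR by construction), matching the cohort's 4.67%
  attrition; `little_mcar_test()` (EM-pooled estimates, chi-square over
  missingness patterns) rejects at the nominal rate on these data.
- **Stage**: multinomial with the cohort's stage distribution
  (10.33/40.61/39.44/9.62% for I--IV); `stage_shift` swaps in a different
  cross-lagged matrix for advanced-stage subjects, giving stage-stratified
  cohorts with known subgroup differences.

Everything is deterministic given `spec$seed`, and generation never
disturbs the caller's RNG stream.

**What the generator does not emulate.** Item-level response processes
(subscales are drawn directly), MNAR dropout, floor/ceiling effects beyond
the zero truncation, and any nonlinearity. The zero truncation itself
mildly distorts the linear model: for heavily truncated subscales (D3 and
D4 at wave 2 have means below one SD of zero) recovered coefficients
attenuate by a few percent, and wave-1 sample means match the *clipped*
normal closed form rather than the nominal means (for D1 the clipped mean
is 3.356 against the nominal 3.30). Tests compare against the clipped-normal
oracle. Passing tests therefore show the pipeline recovers a known sparse
linear ground truth under realistic marginals and attrition — not that the
model is correct for any particular real cohort.

## Numerical and scale choices

- Degenerate inputs fail loudly: constant outcomes or predictors, fewer
  than 30 subjects, missing values reaching the estimator, single-pattern
  input to the MCAR test, empty subgroup splits, and rank requests beyond
  a block's nonzero edges are all errors with named causes.
- `lambda = Inf` is handled as the exact penalty limit (lagged
  coefficients identically zero, covariates still fit); `lambda = 0` is
  refit exactly and matches closed-form least squares to 1e-6; fixed
  positive penalties ride a short warm-start path and match an independent
  coordinate-descent implementation to 1e-6.
- Bootstrap failures inside a resample are recorded and skipped; more than
  10% failures abort the summary.

## Problem sizes in the test suite

The acceptance-style checks run at desk scale, chosen as the package's own
trade-off between Monte-Carlo error and runtime: 50 replicates for
sign-recovery at the study size (n = 426) and for the RMSE-vs-n trend
(n = 200/426/2000); 100 subsamples per drop proportion for the large-n CS
check and 40 (5-fold CV) for the small-n refit variant; 30/12 replicates
with 100 bootstrap resamples each for difference-test size/power; 20
replicates for subgroup recovery. Thresholds on rates use the binomial
envelopes those replicate counts imply. `scripts/acceptance.R` re-runs the
same quantities at slightly smaller replicate counts and writes them as
JSON.

## Known limitations

- Two waves only; no >= 3-wave dynamics, and no cross-sectional
  (Gaussian-graphical) network mode.
- The OR reporting transform is applied to standardized Gaussian
  coefficients by default, so "odds ratio" is a reporting convention
  rather than a literal odds interpretation unless the binomial mode is
  used.
- Printed fixture matrices carry 3-decimal rounding; near-ties in
  centrality sums (the in-EI top pair above) are not resolvable from them.
- The stage comparison dichotomizes stage I/II vs III/IV; finer
  stratification is out of scope.
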