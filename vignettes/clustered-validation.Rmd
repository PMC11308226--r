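---
title: "Clustered validation of prediction models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustered validation of prediction models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iecv)
```

## The problem

A clinical prediction model validated in one external cohort yields one
c-statistic and one calibration assessment — and those numbers depend as much
on *which* cohort was chosen as on the model. Two mechanisms drive this:

1. **Case-mix variation.** Discrimination is bounded by how heterogeneous the
   validation patients are. A cohort of clinically similar patients
   (homogeneous case-mix) depresses the achievable c-statistic even for a
   perfectly specified model.
2. **Between-study heterogeneity.** Differences across studies in predictor
   and outcome definitions, measurement, treatment policy, and unmeasured
   setting effects shift the predictor–outcome relationships themselves,
   surfacing as miscalibration (intercept away from 0, slope away from 1)
   and genuinely degraded discrimination.

With clustered data, leave-one-cluster-out internal–external cross-validation
exploits rather than suffers from this structure: each cluster in turn plays
the role of a predefined external validation cohort. The split is
deterministic (non-random), so results do not depend on iteration order, and
the collection of per-cluster estimates can be meta-analysed into a reference
value with an explicit heterogeneity statement.

## The model and the metrics

The outcome model is ordinary maximum-likelihood logistic regression on a
fixed encoding: age linear per year; WFNS grade IV–V, premorbid hypertension
and aneurysm size ≥ 13 mm as binary indicators; CT Fisher grade categorical
with grade 1 as reference; aneurysm location categorical with ACA as
reference. Reference levels are fixed alphabetically/lowest and recorded in
the model object, since published reports rarely state them. Age enters
linearly: the package's purpose is the validation machinery, not maximal
flexibility of the outcome model, and splines would complicate the
serialization contract (`write_model_json()` / `read_model_json()`) that
lets externally published coefficient vectors be validated without
refitting. Separation is detected (diverging coefficients with exploding
Wald standard errors, or non-convergence at extreme values) and reported —
never silently penalized away.

Per validation cluster the package computes:

- **Harrell's c.** Rank formulation: with average ranks of the predictions,
  `c = (sum of event ranks − n1(n1+1)/2) / (n1 n0)`, identical to exhaustive
  pair enumeration with ties counted ½ at O(n log n) cost. The default
  standard error is the DeLong rank-statistic variance; a percentile
  bootstrap is available. The tie convention (½ everywhere) is stated and
  tested.
- **Model-based c.** For pairs *i < j* with `p_hi = max(p_i, p_j)`,
  `p_lo = min(p_i, p_j)`, the statistic is
  `Σ p_hi (1 − p_lo) / Σ [p_i(1 − p_j) + p_j(1 − p_i)]`, with tied pairs
  contributing ½ of each orientation. Because `p_hi(1−p_lo)` equals
  `p_lo(1−p_hi)` exactly when tied, the pairwise sums collapse to sorted
  cumulative sums, so the package evaluates the statistic *exactly* in
  O(n log n) at any n — no subsampling approximation is needed, and the
  O(n²) enumeration survives only as a test oracle. The tests verify the
  defining property: the model-based c equals the Monte-Carlo expectation of
  Harrell's c over outcomes drawn from the predictions themselves. The
  difference `c − c_model-based` therefore isolates the case-mix
  contribution to a validation result; `single_study_view()` labels a
  cluster as case-mix-driven when this difference is below −0.02, a package
  convention chosen as roughly one conventional SE of a mid-sized validation
  cluster.
- **Calibration intercept and slope.** Logistic regressions of the outcome
  on the validation linear predictor: as a fixed offset (intercept,
  calibration-in-the-large) and with a free slope. Both inherit the ML
  machinery including separation reporting; a constant linear predictor is
  an explicit error for the slope.
- **Calibration curves.** Equal-count quantile bins (default 10, collapsing
  gracefully under ties) plus a natural-spline logistic smooth of the
  outcome on the logit of the prediction, with predictions clipped to
  [0.001, 0.999] before the logit to keep the transform finite. The spline
  smoother (3 df) was chosen over loess because it respects the probability
  scale via the logistic link and is deterministic.

The optimism-corrected benchmark uses Harrell's bootstrap with B = 200
resamples by default: optimism is the mean gap between each refit's apparent
c on its bootstrap sample and its c on the original data; degenerate
resamples are redrawn with a capped retry.

## Random-effects pooling

Per-cluster estimates are pooled with inverse-variance random-effects
weights `1/(se² + τ²)`. c-statistics are pooled on the logit scale with
delta-method SEs `se/(c(1−c))` — the convention of the standard
meta-analysis tooling for concordance indices — while calibration intercepts
and slopes pool on the identity scale; the identity scale remains available
for sensitivity. τ² is estimated by REML (default; a 1-dimensional search of
the restricted likelihood with an explicit boundary check at τ² = 0) or by
the DerSimonian–Laird moment estimator, which has a closed form and is the
one pinned exactly in the tests. Cochran's Q always uses fixed-effect
weights and `I² = max(0, (Q − df)/Q)·100`. Wald 95% CIs are back-transformed,
so logit-scale intervals are asymmetric around c — as expected. When SEs are
reconstructed from printed CIs, `se = (upper − lower)/3.92` on the chosen
scale (`se_from_ci()`), with the bounds logit-transformed first for
c-statistics.

Two properties of these statistics matter when reading the tests:

- Under exact homogeneity (τ = 0), `I²` is a truncated statistic:
  `(Q − df)/Q` is negative about half the time and floored at zero, so its
  *mean* across replicates sits around 10–15% for 14 clusters even with no
  heterogeneity at all. "Approximately zero" in the homogeneity tests is
  therefore a bound (< 20) far below any genuinely heterogeneous setting
  (> 75 in the same tests), not a point value.
- Leave-one-cluster-out calibration intercepts contrast each cluster with
  the *mean of the other k − 1*, which inflates their dispersion by the
  design factor k/(k−1). The heterogeneity-recovery test applies this
  analytic correction before comparing the recovered τ with the injected
  one.

## The synthetic repository

`sahit_like_preset()` mirrors the published structure of the SAHIT data
repository: the 14 study sizes (total n = 11,931), per-study age mean/SD,
WFNS IV–V prevalence (0–0.78), Fisher-grade, aneurysm-size and location
distributions, favorable-outcome targets (0.60–0.92), the outcome scale each
study recorded (GOS, eGOS or mRS), and block-missing predictors where a
study's table reports the variable as unrecorded. Where a study did not
report a variable, the full-cohort marginal is used as the generating
distribution. Category probabilities are study counts normalised over their
reported denominators; structural zeros (e.g. no PCOM aneurysms in two
trials) are kept as near-zero cells so the design stays full-rank after
pooling.

Outcomes are drawn as
`y ~ Bernoulli(logit⁻¹(α + δ_k + m_k · xᵀβ))`, with cluster intercept shift
`δ_k` and slope multiplier `m_k` (defaults: preset-calibrated shifts, m = 1).
This two-parameter heterogeneity — a shift plus a scalar multiplier on the
whole linear predictor rather than per-coefficient perturbations — matches
exactly what the calibration intercept and slope can detect, keeping
parameter-recovery tests interpretable; `tau_intercept`/`tau_slope` add
random heterogeneity on top. The generating coefficients
(`default_true_beta()`) are clinically plausible log-odds magnitudes for
aSAH chosen once (age −0.04/yr, WFNS IV–V −1.3, Fisher 4 −0.9, large
aneurysm −0.5, location effects within ±0.3); the originally published
coefficient values are not publicly available. Each preset cluster's
intercept shift is calibrated by root-finding so its *expected* favorable
fraction matches the published per-study fraction; the implied overall
fraction is 0.792, consistent with the published 80% among patients with
observed outcomes. Ages are truncated-normal on [18, 95] for plausibility —
the tables publish only means and SDs — which leaves the logistic mechanism
untouched. Raw outcome-scale scores are generated by a monotone latent draw
within the favorable/unfavorable band of the cluster's scale, so
dichotomization reproduces the generated outcome exactly and the
outcome-scale layer is exercised end to end.

Two missingness mechanisms are deliberately separate, mirroring how real
registries fail: **block-missingness** (a study never recorded a column) is
part of the cluster spec and applied at generation; **item-level MAR
missingness** (`inject_mar_missingness()`) uses a logistic mechanism driven
by observed age and WFNS grade, with its intercept calibrated by
root-finding to hit the requested marginal rate.

What the generator does *not* emulate: correlations between predictors
within a study beyond those induced by the outcome model, informative
(MNAR) missingness, outcome-assessment timing differences, and per-coefficient
between-study heterogeneity (available only through the slope multiplier).
Passing tests therefore demonstrate that the pipeline recovers what it
injects under a clean MAR, shift-and-scale world — not that any particular
real repository satisfies those assumptions.

## Outcome scales

GOS (1–5), eGOS (1–8) and mRS (0–6) are dichotomized as favorable = GOS 4–5,
eGOS 4–8, mRS 0–3. When several scales are recorded the fixed priority is
GOS > mRS > eGOS; published descriptions list the alternatives to GOS
without ranking them, so the order is a recorded package decision
(deterministic, and surfaced in `select_scale()`'s result). The eGOS is
treated as 8-level: although it is sometimes described as a nine-level
refinement of the GOS, its own dichotomization (4–8 versus 1–3) spans 1–8,
and no ninth level is invented.

## Imputation

`impute_chained()` is chained-equations multiple imputation run **once over
the pooled repository** — not per cluster, and not re-estimated inside each
leave-one-out training set. Imputing before splitting slightly favors the
left-out cluster (its block-missing columns are filled using relationships
learned partly from itself), which can dilute apparent between-cluster
heterogeneity; the package follows this order deliberately because it is the
tractable convention for registries with block-missing columns, and the
alternative (per-training-set imputation) cannot impute a column that is
entirely missing in the validation cluster. Conditional models: Bayesian-draw
linear regression for age (predictive-mean matching optional), logistic
regression with a multivariate-normal posterior coefficient draw for binary
variables, and multinomial regression for Fisher grade and location with
classes drawn from fitted probabilities (without a parameter-uncertainty
draw — a stated approximation). Defaults are m = 5 and 10 cycles; both are
recorded in the result. Downstream, per-imputation estimates combine by
Rubin's rules (`T = W̄ + (1 + 1/m)B`), with c-statistics pooled on the logit
scale.

## Membership model and transportability

The membership model regresses an indicator of validation-cluster
membership on all six predictors plus the dichotomized outcome; its
*apparent* c-statistic on the combined sample measures how distinguishable
the validation sample is (0.5 = exchangeable, 1 = disjoint). The apparent
(in-sample) c is used deliberately — relatedness is a descriptive statement
about these two specific samples, not a prediction task — but it carries the
usual in-sample optimism: with ~12 design columns of pure noise it sits a
little above 0.5 at any sample size. Complete separation is not an error
here; it is the "fully distinct" extreme and is reported as c = 1 with a
flag. Relatedness bands follow the published verbal convention: related
below 0.70, moderately distinct 0.70–0.80, distinct at or above 0.80. The
joint reading with the validation c (satisfactory at ≥ 0.70, a package
convention) yields the four transportability/generalizability labels of
`transportability_report()`.

## Numerical choices and degenerate inputs

- IRLS convergence at deviance tolerance 1e-10, 100 iterations; linear
  predictors clamped at ±700 before exponentiation so probabilities stay
  machine-representable.
- Degenerate outcomes (one class) are errors at fit time and per-cluster
  warnings with NA metrics at validation time; degenerate bootstrap
  resamples are redrawn up to a cap.
- All randomness (generation, MAR injection, imputation, bootstrap) flows
  from explicit integer seeds; equal seeds give byte-identical results, and
  child seeds are derived deterministically so pipeline stages do not share
  streams.
- REML's τ² search brackets [0, max(10·var θ, 10·max v)] with an explicit
  boundary comparison at zero.

## Problem sizes used in the tests

The simulation tests run at sizes chosen to keep Monte-Carlo error well
below the tested tolerances: parameter recovery at n = 50,000; calibration
recovery at n = 100,000; heterogeneity recovery with 14 clusters of 2,000
patients and 60 replicates per τ ∈ {0, 0.3, 0.6}; the optimism-direction
check with 50 replicates of an intentionally overfit 100-patient,
11-column setting; and brute-force oracle comparisons on 200 random
instances of n ≤ 50. The full suite runs in a few minutes on one core.

## Known limitations

- The outcome model is the fixed six-predictor encoding; no splines,
  interactions, or penalization.
- Imputation is single-level (cluster structure is not in the imputation
  model) and multinomial draws omit parameter uncertainty.
- The membership c is apparent and slightly optimistic by construction.
- Meta-analysis offers Wald intervals by default with an optional truncated
  Hartung–Knapp adjustment; no meta-regression or publication-bias
  diagnostics.
- The synthetic repository reproduces published *marginal* structure only;
  conclusions about any real repository require the real patient-level data.
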