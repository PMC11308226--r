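# iecv: internal–external cross-validation of clinical prediction models

`iecv` is an R package for the **clustered validation** of clinical
prediction models for binary outcomes. It is built around a simple
observation: validating a model in a *single* external study gives one draw
from a wide distribution of possible validation results, because studies
differ in case-mix and in predictor–outcome relationships. With clustered
data (multiple studies, registries, regions, or periods),
**leave-one-cluster-out internal–external cross-validation (IECV)** turns one
dataset into many external validations: each cluster is left out of model
development in turn, the model is refitted on the rest and evaluated in the
left-out cluster, and the per-cluster performance estimates are summarised
with random-effects meta-analysis.

The motivating application is prognosis after aneurysmal subarachnoid
hemorrhage (aSAH): a logistic model predicting favorable functional outcome
(dichotomized Glasgow Outcome Scale / modified Rankin Scale) from age, WFNS
grade, premorbid hypertension, CT Fisher grade, and aneurysm size and
location, validated across the 14 studies of the SAHIT (Subarachnoid
Hemorrhage International Trialists) repository. The patient-level repository
is restricted, so the package also ships a **synthetic multi-study
generator** that emulates its published structure (14 clusters of 60–3,552
patients, WFNS IV–V prevalence 0–78%, favorable outcome 60–92%, block-missing
predictors in some studies).

## What it computes

For a model with linear predictor $\hat\ell = \hat\alpha + x^T\hat\beta$ and
predicted risk $\hat p = \mathrm{logit}^{-1}(\hat\ell)$, each validation
cluster gets:

- **Harrell's c-statistic** — $\Pr(\hat p_i > \hat p_j \mid y_i=1, y_j=0)$
  with ties counted ½, computed by an O(n log n) rank method with DeLong
  standard errors;
- **model-based c-statistic** — the concordance *expected if outcomes truly
  followed the predictions*; it depends only on the spread of $\hat p$
  (case-mix), so $\Delta = c - c_{\text{model-based}}$ isolates the case-mix
  contribution to a disappointing (or flattering) validation;
- **calibration intercept** $a$: intercept of `y ~ offset(lp)`
  (calibration-in-the-large, 0 is ideal) and **calibration slope** $b$ from
  `y ~ lp` (1 is ideal, < 1 signals overfitting-type spread), plus grouped
  and smoothed calibration-curve data;
- a bootstrap **optimism-corrected c** benchmark (Harrell's bootstrap);
- a **membership model** (logistic regression of cluster membership on all
  predictors plus the outcome): its c-statistic measures how *distinct* the
  validation sample is from the development sample, and combined with the
  validation c gives a gross transportability/generalizability readout.

Per-cluster estimates are pooled with inverse-variance **random-effects
meta-analysis** (REML or DerSimonian–Laird; c on the logit scale), with
between-cluster heterogeneity reported as $\tau^2$, Cochran's Q, and
$I^2 = \max(0, (Q - df)/Q) \cdot 100$. Missing predictors (item-level or
whole columns per study) are handled by chained-equations multiple
imputation with Rubin's-rules pooling.

## Worked example

```r
library(iecv)

# a SAHIT-like synthetic repository: 14 studies, n = 11,931
data <- generate_dataset(sahit_like_preset(seed = 1))

# leave-one-cluster-out cross-validation (block-missing predictors
# are multiply imputed first)
res <- loco_cv(data, m = 1, iterations = 3, seed = 1)

# pool the per-cluster c-statistics on the logit scale
cs <- dplyr::filter(tidy(res), metric == "c")
meta_pool(cs, transform = "logit", method = "REML")
#> Random-effects pooling (REML, logit scale) of 14 clusters
#>   pooled 0.712 (95% CI 0.695 to 0.729)
#>   tau^2 0.0073; Q 21.69 on 13 df; I^2 40%
```

The pooled c of 0.71 is the reference for expected external performance of
the model across settings; the I² of 40% says a moderate share of the
spread in per-cluster c's reflects real between-study heterogeneity rather
than sampling error. `single_study_view(res, "IMASH")` then decomposes any
single cluster's result into case-mix and miscalibration contributions, and
`membership_by_cluster()` + `transportability_report()` add the relatedness
reading.

The published per-study validation summaries of the SAHIT model ship with
the package:

```r
t2 <- sahit_performance()
meta_pool(t2$c, se = se_from_ci(t2$c_low, t2$c_high, "logit"),
          transform = "logit", se_scale = "transformed")
#>   pooled 0.742 (95% CI 0.697 to 0.782)
#>   tau^2 0.1389; Q 138.79 on 13 df; I^2 91%
range(t2$c)
#> [1] 0.52 0.84
```

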