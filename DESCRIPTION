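Package: iecv
Title: Internal-External Cross-Validation of Clinical Prediction Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clustered validation of clinical prediction models for binary
    outcomes. Provides leave-one-cluster-out internal-external
    cross-validation, single-study external validation reports,
    discrimination (Harrell's c and the model-based c-statistic) and
    calibration (intercept, slope, calibration curves), random-effects
    meta-analytic pooling of per-cluster performance with Cochran's Q and
    the I-squared statistic, bootstrap optimism correction, membership
    models for relatedness and transportability, chained-equations multiple
    imputation with Rubin's-rules pooling, and a synthetic multi-study data
    generator emulating the case-mix heterogeneity of a large aneurysmal
    subarachnoid hemorrhage trial repository.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    splines,
    utils,
    nnet,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
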