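Package: clpnet
Title: Cross-Lagged Panel Networks for Two-Wave Symptom Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimation, centrality, stability and subgroup comparison for
    cross-lagged panel networks (CLPN) over two-wave psychological symptom
    data. One penalized regression per wave-2 outcome on all wave-1
    subscales (LASSO via glmnet, covariate-adjusted) yields a directed
    temporal network; odds-ratio edge reporting, in/out expected influence
    and one-step bridge expected influence, nonparametric bootstrap edge
    confidence intervals, case-dropping correlation-stability (CS)
    coefficients, edge and centrality difference tests, and stage-stratified
    network comparison. Includes a calibrated synthetic two-wave cohort
    generator with known ground truth, subscale scoring and reliability
    helpers, Little's MCAR test, and worked-example fixtures from a
    two-wave breast-cancer psycho-oncology cohort (death anxiety and fear
    of cancer recurrence subscales).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
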