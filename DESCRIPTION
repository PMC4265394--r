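Package: predictebc
Title: Prognostication and Treatment-Benefit Modelling for Early Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multiplicative proportional-hazards prognostic model
    for early breast cancer in two forms: a clinicopathological model with
    HER2 status (v2) and an extension adding KI67 status via mean-one marker
    renormalization (v3). Computes per-patient annual breast-cancer and
    other-cause survival under competing risks, cumulative cause-specific
    mortality, and absolute adjuvant-therapy benefits at 5 and 10 years.
    Ships the validation toolkit used to assess such models: observed
    versus expected calibration by clinical strata and predicted-risk
    quantiles with exact Poisson intervals, chi-squared goodness of fit,
    horizon-restricted ROC/AUC, and DeLong's test for comparing correlated
    AUCs. A synthetic-cohort module generates cohorts with realistic
    covariate marginals, missingness, and piecewise-exponential outcomes so
    the whole pipeline is exercisable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
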