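Package: proxrisk
Title: Temporal-Proximity Versus Lagged Models of Dynamic Violence Risk Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing predictive (lagged) and temporal-proximity
    (causal) models of dynamic risk and protective factors for violence in
    longitudinal forensic cohorts. Provides a synthetic-cohort generator with a
    distal-to-proximal causal structure, builders for lagged, concurrent and
    static exposure-outcome designs, clustered Somers'-D/AUC discrimination with
    cluster-jackknife inference, nested random-intercept logistic regression via
    'lme4', an explanatory-variable screening and coefficient-attenuation
    procedure, and a one-call pipeline producing the full set of comparison
    tables and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
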