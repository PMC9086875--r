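Package: boxcua
Title: Trial-Based Cost-Utility Analysis of Remote Monitoring After
    Myocardial Infarction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Patient-level cost-utility analysis of an eHealth remote
    monitoring programme ("The Box") versus regular outpatient follow-up
    after acute myocardial infarction, from a department-of-cardiology
    perspective over one year.  Provides a calibrated synthetic trial
    generator (two-part per-item cost models, correlated utility
    trajectories with missing-at-random dropout), micro-costing with
    overhead allocation and a configurable price table, quality-adjusted
    life years by the trapezoidal area-under-the-curve method with
    multiple imputation and Rubin pooling, nonparametric within-arm
    bootstrap of incremental costs and effects, cost-effectiveness
    planes and acceptability curves, and a patient-related-cost
    sensitivity analysis, orchestrated by reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
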