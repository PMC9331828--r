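Package: fcsscreen
Title: Rule-Based Screening and Machine-Learning Benchmarks for Familial
    Chylomicronemia Syndrome in Longitudinal Hospital Records
Version: 0.1.0
Authors@R:
    person("FCS", "Screen Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Operationalizes the Moulin familial chylomicronemia syndrome
    (FCS) diagnostic score on longitudinal electronic health records:
    per-patient scoring from dated laboratory measurements and ICD-10
    diagnosis events, a rapid cascading population filter with running
    score attribution, cohort score-distribution and prevalence reporting
    in the field's rate units (percent, per mille, per ten thousand, pcm,
    ppm), a seeded synthetic-cohort generator with planted FCS, MFCS-like
    and background strata, and a repeated train/test machine-learning
    benchmark (gradient boosted trees, adaptive boosting, kernel machine,
    rectified-linear network) with depth-weighted feature-importance
    ranking and laboratory decision-cut extraction from early trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
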