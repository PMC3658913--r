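Package: dietcalib
Title: Biomarker Calibration of Self-Reported Dietary Intake with
    Psychosocial Covariates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Measurement-error modelling for self-reported dietary intake
    anchored to recovery biomarkers (doubly labeled water for energy,
    urinary nitrogen for protein). Provides a synthetic-cohort generator
    emulating a biomarker validation study in postmenopausal women,
    scoring of psychosocial instruments (Crowne-Marlowe social
    desirability, TFEQ-R18 eating scales, body-silhouette discordance,
    percent of meals eaten at home), bias regressions of self-report minus
    biomarker on participant characteristics, regression-calibration
    equations with sequential R-squared decomposition over covariate
    groups, a reliability-replicate adjusted R-squared with sensitivity to
    the replicate-error correlation, and bootstrap inference for the
    change in R-squared between nested calibration equations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
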