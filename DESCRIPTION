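Package: icapacity
Title: Intrinsic-Capacity Scoring and Longitudinal Prediction for Aging Cohorts
Version: 0.1.0
Authors@R: person("Platform", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Scores the five WHO intrinsic-capacity (IC) domains (locomotion,
    sensory, psychological, cognition, vitality) on the unit interval from
    standard geriatric instruments (SPPB, self-rated hearing/vision, PHQ-9,
    MOCA, SF-12 energy item plus grip strength), builds longitudinal
    supervised datasets by pairing wave-t questionnaire features with
    wave-(t+h) IC labels, and benchmarks four regressor families (ordinary
    least squares, random forest, gradient boosting, dense neural network)
    under 10-fold cross-validation with MSE/MAE/R2/MedAE reporting. Includes
    a synthetic multi-wave cohort generator with controllable decline,
    noise, missingness and dropout so the full pipeline is testable without
    access to restricted panel data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
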