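Package: sf12risk
Title: Depression-Risk Modelling from SF-12 Surveys in Cardiac-Surgery Cohorts
Version: 0.1.0
Authors@R:
    person("Maintainer", "sf12risk", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores SF-12v2 health-survey responses into eight domain scores
    and norm-based physical and mental component summaries (PCS/MCS), flags
    depression risk via the MCS < 42 screening rule, and models that risk in
    post-cardiac-surgery cohorts. Provides five dimensionality-reduction
    estimators under one contract (PCA, kernel PCA, gradient/Hebbian PCA,
    centroid-class PCA, and an LDA hybrid), a cross-validated classifier
    benchmark over reduced feature spaces, a CART risk tree reporting
    a-priori and a-posteriori node risks, and a seeded synthetic-cohort
    generator calibrated to published cohort marginals so the full pipeline
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    FNN,
    quadprog,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster
Config/testthat/edition: 3
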