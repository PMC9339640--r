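Package: soctmi
Title: Sparse-Orthogonal-Collimator Total Marrow Irradiation Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Inverse treatment planning for preclinical total marrow
    irradiation (TMI) on kilovoltage small-animal irradiators. Provides a
    deterministic synthetic digital mouse phantom, a heterogeneity-corrected
    kV beamlet dose engine (Siddon ray tracing with a Gaussian lateral
    kernel), FISTA-based fluence-map optimization with a rectangle-promoting
    total-variation regularizer and greedy decomposition of fluence maps into
    weighted rectangular apertures deliverable by four orthogonal leaf pairs,
    a parallel-opposed fixed-collimator 3D-TMI baseline planner with field
    matching and junction hot-spot reporting, and dose-volume-histogram and
    median/integral-dose analytics for cohort summaries and paired plan
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
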