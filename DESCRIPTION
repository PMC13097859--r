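Package: imusway
Title: Functional Movement Assessment from Wearable Inertial Sensors in
    Vestibulopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for six-axis inertial measurement unit (IMU)
    recordings of daily-living tasks in bilateral vestibulopathy, unilateral
    vestibulopathy and healthy control groups. Provides trial-level signal
    preprocessing (edge trimming, zero-phase Butterworth low-pass filtering),
    formula-defined movement features (RMS of 3D acceleration and angular
    velocity norms, sway jerkiness, segment-to-segment attenuation
    coefficients, task duration), dual-criterion nonparametric task selection
    (Kruskal-Wallis with Dunn-Holm post hoc tests on task duration and
    perceived difficulty), principal component analysis with permutation-based
    component retention and bootstrap loading-stability diagnostics, and a
    three-group discriminant screen of the component-selected variables. A
    synthetic cohort generator with a planted ground-truth effect registry
    allows the whole pipeline to be exercised and validated without access to
    clinical recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
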