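Package: protonKBP
Title: Knowledge-Based Treatment Planning for Intensity-Modulated Proton
    Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for proton-specific knowledge-based treatment planning.
    From a library of intensity-modulated proton therapy (IMPT) plans the
    package learns a principal-component regression between geometry-based
    expected dose (GED) features and achieved organ-at-risk dose-volume
    histograms (DVHs), predicts DVH bands for new cases, places optimization
    objectives at the lower prediction boundary, generates knowledge-based
    plans with a simplified spread-out-Bragg-peak dose engine, and evaluates
    them with standard plan-quality endpoints (homogeneity index, V95, mean
    and maximum dose). Includes a seeded generator of head-and-neck-like
    synthetic phantom cohorts so the full pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Matrix,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
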