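Package: gaitsym
Title: Gait Symmetry Assessment from Vertical Ground Reaction Forces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying left-right gait symmetry from stance-phase
    vertical ground reaction force (GRF) recordings. Implements the classical
    per-parameter protocol (coefficient of variation, Robinson's absolute
    symmetry index, paired t-tests on the six discrete gait parameters
    Fz1/Tz1/Fz2/Tz2/Fz3/Tz3) alongside a classification-based approach in
    which a soft-margin kernel support vector machine, trained by sequential
    minimal optimization, discriminates left from right 101-point normalized
    stance curves; above-chance cross-validated accuracy evidences asymmetry.
    A synthetic cohort generator emulating two-peak vertical GRF waveforms
    with controllable left-right asymmetry supports validation and power
    studies without force-platform data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
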