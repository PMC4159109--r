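Package: pcdrupture
Title: Passive Cavitation Detection for Predicting and Suppressing
    Vessel Rupture During Focused Ultrasound Exposure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies passively detected acoustic cavitation emissions
    recorded during high-intensity focused ultrasound (HIFU) exposure of
    blood vessels: segmented periodogram averaging with band-integrated,
    noise-normalized emission levels (low-frequency, broadband, and
    subharmonic), flow-meter based rupture detection and pre-rupture
    labeling, ROC analysis with corner-threshold selection, a model of the
    analog subharmonic monitoring chain (bandpass, amplification,
    rectification, AM demodulation), and a closed-loop feedback controller
    that modulates exposure intensity against a synthetic vessel-rupture
    model. Includes the statistical procedures used to summarize rupture
    time experiments (signed-rank test with Pratt zero handling, paired and
    pooled t tests, Fisher exact tests) and a fully seeded synthetic data
    generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    arrow,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
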