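Package: loometry
Title: Behavioral and Photometric Analysis of Visual Looming Threat Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing visual looming-threat extinction and
    updating experiments in mice. Models looming/dimming stimulus
    schedules as event timelines, scores freezing, sheltering and flight
    ethograms from pose-estimation keypoint tables, processes two-channel
    (465/405 nm) fiber-photometry recordings into motion-corrected zdFF
    traces (moving-mean smoothing, airPLS baseline removal,
    standardization, non-negative robust isosbestic regression), computes
    stimulus-locked summaries (peri-event matrices, pre/post AUC,
    magnitude spectra, behavior-triggered averages), couples neural
    signal to behavior (logistic and linear regression with confidence
    bands), and quantifies engram reactivation from c-Fos/EYFP cell
    counts with Benjamini-Hochberg FDR control. Seeded synthetic-data
    generators with recorded ground truth support parameter-recovery
    testing of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    jsonlite,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    pracma,
    glmnet
Config/testthat/edition: 3
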