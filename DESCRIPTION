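Package: placomp
Title: Compositional Analysis of Placental Cell Types and Prenatal Air Pollution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links trimester-average fine particulate matter (PM2.5) exposure to
    placental cell-type composition inferred from bulk DNA methylation.
    Provides reference-based cell-type deconvolution by constrained projection
    (nonnegative least squares with a sum-to-at-most-one simplex constraint),
    multiplicative replacement of rounded zeros, isometric log-ratio (ilr)
    compositional regression with case-resampling bootstrap inference
    (percentile confidence intervals and a bootstrap-corrected median-F overall
    test), per-cell-type beta regression by maximum likelihood, and a seeded
    synthetic-data generator that emulates a pregnancy cohort's statistical
    structure so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    quadprog,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
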