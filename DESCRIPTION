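Package: optoret
Title: Phase-Based Optoretinography Analysis and Test-Retest Repeatability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for phase-based optoretinography (ORG) with adaptive-optics
    optical coherence tomography (AO-OCT): simulation of complex two-layer cone
    photoreceptor signals with realistic phase noise, bulk axial motion and eye
    movement dropout; extraction of outer-segment optical path length changes
    via the conjugate-product phase-difference estimator with circular baseline
    referencing and temporal unwrapping; overdamped-oscillator
    (difference-of-exponentials) response model fitting with RMS-error
    filtering; and single-cone and pooled test-retest repeatability statistics
    (coefficient of variation, intraclass correlation ICC(2,1) with
    F-distribution confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
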