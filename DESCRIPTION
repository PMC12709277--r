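Package: halocell
Title: Adaptive-Threshold Segmentation of Phase-Contrast Stem Cell Images
    with Halo Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of adherent stem cells in phase-contrast microscopy
    images. Implements local-contrast preprocessing, an adaptive histogram
    threshold model driven by the rate of rise and peak position of the
    contrast distribution, area-based mask constraints, and an iterative
    halo-correction step that refines the cell contour by following
    directional intensity gradients to the halo ridge. Includes pixel-level
    evaluation metrics, confluency estimation, a seeded synthetic
    phase-contrast phantom generator with ground-truth masks, and a
    command-line interface for batch segmentation, evaluation, simulation,
    and parameter calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
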