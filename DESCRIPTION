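Package: chromROI
Title: Genetic-Algorithm Region-of-Interest Selection for Chromatogram Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Selects the regions of a heterogeneous two-dimensional
    chromatogram image (for example a GCxGC-TOF-MS pseudo-color heat map)
    whose color variability carries an analytical signal. Images are
    partitioned into a rectangular grid of subimages; a genetic algorithm
    searches binary subimage subsets, scoring each subset by the
    leave-one-out cross-validation error of a PLS1 regression built on
    pooled color-frequency histograms (grayscale, RGB and/or HSV). The
    winning histogram can be refined by interval PLS (iPLS) and by
    interval selection via the successive projections algorithm
    (iSPA-PLS). Calibration/prediction splitting follows the SPXY
    algorithm on joint predictor-response distances, and full figures of
    merit (RMSECV, RMSEP, REP, R-squared and a one-sided bias t-test) are
    reported. A synthetic-image generator with planted response-correlated
    regions supports validation without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    png,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
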