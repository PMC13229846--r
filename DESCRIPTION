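Package: carotlab
Title: Pigment Prediction from Calibrated Root Colour Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An image-analysis workflow for predicting carotenoid and
    anthocyanin content of carrot roots from digital photographs. Images
    containing a 24-chip colour checker are calibrated per light condition
    with a quadratic cross-band regression, disk colours are extracted from
    polygonal regions of interest, converted to CIELab/LCh, and related to
    spectrophotometric pigment assays (Lichtenthaler total carotenoids,
    pH-differential total monomeric anthocyanins) through partial least
    squares regression with 10-segment cross-validation. A synthetic-study
    generator renders complete checker-plus-disk scenes with known colour
    and pigment ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    mixOmics,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
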