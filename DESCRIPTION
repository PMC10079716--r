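Package: hipcalib
Title: Bi-Planar Radiograph Calibration for Hip Arthroplasty Templating
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Projective-geometry calibration of the hip-plane magnification
    (calibration factor) from a spherical external marker measured in paired
    anteroposterior and lateral radiographs, for pre-operative templating of
    total hip arthroplasty. Provides an exact cone-beam forward model of
    sphere-to-ellipse projection, the iterative single-marker solver used for
    the internal reference marker, the bi-planar external-marker solver, a
    virtual phantom simulator reproducing a 12-position by 4-rotation
    factorial proof-of-concept design, and a statistical pipeline (descriptive
    summaries, minimal-clinically-important-difference counts, paired t and
    Kruskal-Wallis tests, intraclass correlation coefficients).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
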