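Package: mppscore
Title: Modified Polsby-Popper Shape Scoring of Tumor Compartments in
    Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies the waviness and disjointedness of tumor tissue
    compartments on histology sections with the modified Polsby-Popper
    (MPP) score, a log-transformed isoperimetric quotient computed from
    the total perimeter and total area of all tumor annotations on a
    slide. Provides sub-pixel geometry extraction from labeled raster
    masks and viewer-exported GeoJSON annotations, a reproducible
    superpixel-plus-scribble tissue classification stage with a
    computer-assisted stromal ratio, analytic synthetic shape and
    histology-image generators with closed-form oracles, a calibrated
    synthetic clinicopathologic cohort generator, and the accompanying
    statistical layer (quantile dichotomization, Kaplan-Meier and
    log-rank analysis, reverse Kaplan-Meier follow-up, effect sizes,
    and paired DeLong ROC-AUC comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    grDevices,
    utils,
    jsonlite,
    png,
    tiff,
    survival,
    pROC,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
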