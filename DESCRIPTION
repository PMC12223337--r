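Package: trichovision
Title: Vision Pipeline for Classifying Cannabis Non-Glandular Trichomes in
    Microscope Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a microscope image of plant material
    shows genuine cannabis non-glandular trichomes ("real") or trichomes of
    non-cannabis plant material ("fake"), the forensic screening task where
    synthetic cannabinoids are sprayed onto inert plant matter.  Provides
    YOLO-format bounding-box annotation input/output with plant-level
    (leakage-free) dataset splitting, a synthetic microscope-scene generator
    with per-class trichome morphology (curvature, width, density,
    cystoliths), compiled convolutional network classifiers (a basic CNN and
    a deep-layer-aggregation variant) trained with Adam and validation-based
    model selection, a detector-backend contract with a classical
    curvature-based detector and a mock backend, the detection-count decision
    scheme mapping detections to an image label, two-stage and three-stage
    detector-classifier cascades with patch extraction, and split-averaged
    accuracy reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
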