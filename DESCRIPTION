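Package: weedspec
Title: Hyperspectral Weed Species Identification from VNIR Reflectance Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for identifying weed species from visible/
    near-infrared (400-1000 nm) hyperspectral reflectance images. Provides a
    synthetic hypercube and region-of-interest generator emulating the
    spectral structure of nine common arable weed species, ENVI-format cube
    input/output with dark/white reference calibration, moving-average
    smoothing and standard normal variate (SNV) scatter correction,
    pixel-level principal component analysis with variance accounting, a
    battery of descriptive spectral-signature statistics (reflectance range,
    spectral bandwidth, contrast ratio, relative bandwidth, normalised
    contrast), plant-wise grouped train/test splitting, five classifiers
    (random forest, linear SVM, single-hidden-layer neural network,
    maximum-entropy multinomial logistic regression, and SIMCA) and a full
    evaluation surface (confusion matrices, precision/recall/F1, macro and
    micro accuracy, log loss and log-loss reduction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    e1071,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
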