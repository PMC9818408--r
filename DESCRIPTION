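Package: swequant
Title: Quantitative Analysis of Shear-Wave Elastography Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative group analysis of color-coded shear-wave
    elastography (SWE) images of muscle. Reconstructs per-pixel shear-wave
    velocity by inverting the elastogram color scale, extracts a 323-column
    handcrafted feature representation (channel statistics, stiffness-band
    pixel counts, Gabor texture features, over the whole image and ten
    horizontal depth segments, plus activity and session indicators),
    benchmarks six classifiers under repeated nested cross-validation with
    empirical-quantile confidence intervals and Gini feature importances, and
    localizes group stiffness differences with pixelwise mean summary images
    and Hotelling's T-squared significance maps. Includes a synthetic
    elastogram generator emulating a two-group repeated-measures imaging
    study for end-to-end testing and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    glmnet,
    graphics,
    grDevices,
    jsonlite,
    png,
    ranger,
    Rcpp,
    rpart,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
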