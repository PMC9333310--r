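Package: standcount
Title: Image-Based Plant Stand Counting by Density-Map Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates plant stand counts (emerged plants per plot) from RGB
    field images of maize at early vegetative stages. Point annotations of
    plant centers are converted to ground-truth density maps with
    geometry-adaptive Gaussian kernels; a fully convolutional network with a
    truncated VGG-16 backbone, multi-scale feature fusion and transposed
    convolution upsampling regresses the density map, and the stand count is
    the map's integral. Includes LabelMe-style annotation I/O, a multi-scale
    patch augmentation pipeline, peak-detection and non-maximum-suppression
    post-processing for per-plant detections, count-error metrics (MAE, RMSE,
    MAPE, bias) with growth-stage stratification, and a synthetic field-image
    generator for fully reproducible end-to-end runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    jpeg,
    yaml,
    readr,
    withr,
    EBImage,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
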