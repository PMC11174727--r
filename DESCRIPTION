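Package: bagseg
Title: Bagged Deep-Learning Semantic Segmentation for Crop Phenotyping Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for separating crop from background pixels in field
    phenotyping RGB imagery. Implements a compact encoder-decoder
    convolutional segmentation network with multi-rate dilated (atrous)
    spatial pyramid pooling, trained with cross-entropy loss and geometric
    augmentation, and a bagging ensemble that fuses estimators trained on
    distinct train/validation splits by per-pixel majority vote. Includes
    two classical baselines (HSV hue-range thresholding fitted by SSE grid
    search, and a random-forest pixel classifier on RGB plus gray-level
    co-occurrence matrix texture features of the 7x7 neighborhood),
    intersection-over-union evaluation, estimator-count and
    labeled-sample-size learning curves with Student-t confidence bands,
    and a synthetic maize-field image generator for fully reproducible
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    randomForest,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
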