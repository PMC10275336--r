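Package: fascseg
Title: Fascicle Segmentation and Evaluation for Peripheral-Nerve MicroCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for semantic segmentation of nerve
    fascicles in 16-bit microCT cross-sections of peripheral nerves and,
    centrally, for evaluating such segmentations. Provides a reproducible
    synthetic nerve-phantom generator (bright fascicle blobs inside an
    epineurium sheath, per-slice brightness drift, staining-artifact
    specks, merge/split events along the stack axis), stack input/output
    with the every-tenth-slice down-sampling rule, grouped leave-one-out
    cross-validation splits, the preprocessing chain (border-slice
    exclusion, centroid centering and cropping, saturation-aware 16-to-8
    bit contrast enhancement, mean normalization, Gaussian smoothing),
    on-the-fly compound augmentation, a from-scratch Dice-loss U-Net
    trained with Adam and a stepped learning-rate schedule, and an
    evaluation framework covering pixel-wise Dice/precision/recall with
    threshold sweeps and fascicle-wise IoU-matrix matching with detection
    F1 and a missed/added/merged/split error taxonomy stratified by
    fascicle size.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    tiff,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
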