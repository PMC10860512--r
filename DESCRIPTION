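Package: gtvseg
Title: Transfer Learning for Lung Gross Tumour Volume Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for studying domain adaptation of deep
    segmentation models for lung gross tumour volume (GTV) delineation on CT.
    Provides a synthetic two-domain CT phantom generator with simulated
    multi-observer delineations, a 2D attention U-Net with Dice-loss training
    implemented natively (RcppArmadillo convolution kernels, hand-derived
    backpropagation), a fine-tuning protocol with a catastrophic-forgetting
    guard, volume-level geometric evaluation (Dice, precision, recall,
    pairwise inter-observer agreement, consensus-region recall), and
    one-way ANOVA with Tukey HSD reporting of method differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
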