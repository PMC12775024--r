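Package: fawfusion
Title: Multimodal RGB-Thermal Image Fusion for Fall Armyworm Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A dual-path pipeline for classifying fall armyworm (Spodoptera
    frugiperda) infestation in maize from paired RGB and thermal leaf images.
    One path extracts 256-dimensional features per modality with small
    convolutional networks, concatenates them, and classifies the fused
    512-vector with a deep neural network; the other stacks the two
    modalities into a 6-channel image classified by a vision transformer
    with a widened patch embedding. Includes aspect-preserving preprocessing,
    a seed-deterministic synthetic paired-image generator with ground-truth
    lesion and hotspot masks, evaluation (confusion-matrix metrics, ROC/AUC,
    precision-recall curves, stratified K-fold cross-validation), PCA
    feature-space visualization, and a four-arm ablation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    ggplot2,
    grDevices,
    graphics,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
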