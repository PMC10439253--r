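Package: dlrs
Title: Deep-Learning Radiomics Scoring of Tumor Microenvironment from CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict a binary tumor-microenvironment class from
    contrast-enhanced CT. Implements CT preprocessing (trilinear resampling,
    Hounsfield-unit window normalization, tumor-centred 64x64 model inputs),
    a 361-feature hand-crafted radiomics bank (shape, first-order, GLCM,
    GLRLM, GLSZM, GLDM over four gray-level discretizations), a
    multi-resolution convolutional network with squeeze-and-excitation
    channel attention fused with the radiomics vector, focal-loss training
    with Adam and a halving learning-rate schedule, threshold selection by
    the Youden index, full diagnostic evaluation (ROC/AUC with bootstrap
    confidence intervals, calibration and decision curves), Guided Grad-CAM
    saliency maps, and a synthetic CT phantom generator so the whole
    pipeline is testable without protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
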