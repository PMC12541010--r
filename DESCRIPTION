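Package: acunet
Title: Attention-Gated Convolutional U-Net for Brain Tumor Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 2D attention-based convolutional U-Net for multi-modal MRI
    brain-tumor segmentation, with dual parallel spatial and channel attention
    modules, attention-gated skip connections, a combined Dice and
    cross-entropy loss, and region-wise evaluation (Dice, Jaccard,
    sensitivity, specificity, HD95, ASSD) over the nested whole-tumor,
    tumor-core and enhancing-tumor regions. Includes NIfTI volume handling,
    slice extraction and preprocessing, a seeded multi-modal phantom
    generator for end-to-end testing without external data, seeded SGD
    training with k-fold cross-validation, an ablation harness over the
    attention variants, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
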