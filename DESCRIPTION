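Package: attnvgg
Title: Attention-Gated VGG16 Classification of Breast Ultrasound Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies benign versus malignant breast-ultrasound lesions with
    an additive attention gate grafted onto a modified VGG16 convolutional
    backbone, trained with a weighted ensemble of cross-entropy and
    log-hyperbolic-cosine losses. Ships a synthetic speckle-noise lesion-image
    generator so the full pipeline (preprocessing, stratified splitting,
    training with RMSprop, six-metric confusion-matrix evaluation including
    the Matthews correlation coefficient, and a model-by-loss comparison
    grid) runs end to end without any external imaging data. The network,
    its gradients and the optimiser are implemented directly on BLAS-backed
    matrix operations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
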