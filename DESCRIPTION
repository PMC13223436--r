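Package: pneumonet
Title: Hybrid Fire-Module/Attention Networks with Adaptive Dropout for
    Pneumonia Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains and evaluates a compact hybrid image classifier for
    four-class pneumonia screening on grayscale chest X-ray and CT images.
    The network chains SqueezeNet-style fire modules, a patch-token
    self-attention stage, and a depthwise-separable residual block with a
    global-average-pooling softmax head; all forward and backward passes are
    implemented in base R on BLAS-backed matrix products.  A population
    metaheuristic combining water-strider exploration with arithmetic
    crossover and Gaussian mutation tunes the shared dropout rate during
    training.  Includes a deterministic synthetic chest-image generator with
    ground-truth lesion masks, the standard preprocessing chain (histogram
    equalization, bilinear resizing, z-score normalization, augmentation),
    stratified k-fold cross-validation, a full metrics panel (confusion
    matrix, per-class and macro scores, one-vs-rest AUC, one-way ANOVA), and
    Grad-CAM saliency maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
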