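Package: lungkit
Title: Contrast Enhancement and Small-CNN Classification of Chest CT and
    X-Ray Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a pixel-probability contrast-enhancement operator for
    low-contrast chest CT and X-ray images, built from a truncated k-symbol
    Lerch transcendent weighting of each pixel by the Pochhammer k-symbol of
    its global-histogram probability. Provides quality-metric-driven selection
    of the fractional exponent via a grid sweep, a self-contained four-layer
    convolutional neural network (batch normalization, ReLU, max pooling,
    softmax) trained with stochastic gradient descent with momentum and early
    stopping, stratified holdout and five-fold cross-validation protocols, a
    kernel-filter ablation harness, confusion-matrix evaluation metrics, and
    seeded synthetic phantom and texture-class generators so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    EBImage,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'cnn.R'
    'fixtures.R'
    'io.R'
    'kltf.R'
    'metrics.R'
    'protocol.R'
    'quality.R'
    'zzz.R'
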