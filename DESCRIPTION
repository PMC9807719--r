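Package: btcfcnn
Title: Fast Convolutional Networks for Brain-Tumor MRI Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Declarative specification, exact parameter and
    multiply-accumulate cost auditing, and a trainable runtime for small
    sequential convolutional networks aimed at multi-class brain-tumor
    classification from T1-weighted MRI slices. Provides the canonical
    13-layer BTC-fCNN architecture with 1x1 convolution bottlenecks, three
    cross-validation training protocols (plain five-fold, iterated transfer
    learning, and fold-to-fold internal transfer learning with an explicit
    train/test leakage audit), confusion-matrix evaluation metrics, readers
    for the Figshare brain-tumor dataset layout and generic image
    directories, and a seeded synthetic phantom generator so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    rlang,
    withr,
    stats,
    utils,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
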