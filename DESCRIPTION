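Package: fsgain
Title: Feature Similarity Gain Attention in Convolutional Network Models of Vision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements the feature similarity gain model (FSGM) of visual
    attention inside a layered convolutional network, together with a
    gradient-based alternative and the downstream analyses used to study
    both: orientation/color grating stimulus generation, a small
    CPU-trainable convolutional fixture network with binary, color and
    softmax readouts, feature-map tuning and gradient value tables,
    multiplicative/additive and feature/spatial attention application,
    detection performance and signal detection theory metrics (criteria,
    sensitivity, ROC sweeps), activity-ratio slope/intercept diagnostics
    separating feature-similarity-gain from feature-matching behaviour,
    and activity-performance correlation with bootstrap comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
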