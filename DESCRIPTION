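Package: crmap
Title: Class-Selective Relevance Mapping for Convolutional Neural Networks
Version: 0.1.0
Authors@R:
    person("crmap", "developers", email = "crmap@example.org", role = c("aut", "cre"))
Description: Localizes the discriminative regions that drive a convolutional
    neural network's class predictions. Implements the class-selective
    relevance map (CRM), which scores every spatial element of the last
    convolutional layer's feature maps by the total squared change it induces
    across all output-class scores when removed, together with class
    activation mapping (CAM) and gradient-weighted CAM (Grad-CAM) baselines,
    class-level averaged relevance maps, heatmap normalization, thresholded
    region-of-interest extraction with bounding boxes, and localization
    evaluation statistics. Ships a seeded synthetic seven-class image
    generator emulating medical imaging modalities and a small CPU-trainable
    CNN with the required convolution, global-average-pooling, dense head so
    the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
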