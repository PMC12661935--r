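Package: teabloom
Title: Tea Flower Detection, Counting and Flowering-Stage Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for quantifying tea (Camellia sinensis)
    flowering from RGB images. Implements a single-stage anchor-based flower
    detector for the three phenological classes (bud, blooming flower,
    withered flower) built from squeeze-and-excitation channel attention,
    adaptive rectangular convolution with bilinear sampling, and a coordinate
    attention + attention-free-transformer block; the full detection and
    counting metric suite (precision, recall, F1, AP, mAP at fixed and ranged
    IoU thresholds, counting R-squared); a small feed-forward classifier that
    maps per-image flower counts and time to one of five flowering stages;
    and seeded synthetic generators for tea-flower scenes and flowering
    seasons so every component is testable without field imagery. All neural
    network forward and backward passes are implemented in the package via
    Rcpp/RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
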