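Package: skelact
Title: Skeleton-Driven Action Recognition from Color-Image Encodings of
    Joint Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encodes sequences of 3D skeleton joint coordinates into compact
    15 x 32 x 3 color-image representations (rows = joints, columns = frames,
    channels = normalized x/y/z) and classifies them with a small
    convolutional neural network built around global average pooling.
    Provides the canonical 15-joint skeleton model, a registry of joint-row
    orderings for studying how joint order in the image affects accuracy,
    a seeded kinematic simulator of seated typical and stereotypical
    behaviors (hand waving, body rocking, covering the ears, and six typical
    actions), cross-subject evaluation with multiclass Matthews correlation,
    a repeated-runs experiment harness with one-way ANOVA and pairwise
    t-tests, class activation maps, and a sliding-window stream classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    png,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
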