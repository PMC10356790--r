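Package: bagnet3d
Title: Position-Gated Bag-of-Local-Features Networks for 3D Brain Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint pathological-region localization and image-level disease
    classification for template-aligned 3D brain volumes. Implements
    receptive-field-limited 3D convolutional encoders that score every
    patch of a volume (a bag of local features), a coordinate-conditioned
    gating branch that learns an inter-subject-consistent discriminative
    probability map, normalized gate-weighted pooling of patch responses
    into an image-level prediction, and end-to-end training with a
    balanced label-smoothed cross-entropy objective plus a gate-entropy
    regularizer. Includes exact receptive-field arithmetic with a
    gradient-based oracle, a synthetic phantom generator with planted
    lesions and distractors, evidence-map export to NIfTI, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
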