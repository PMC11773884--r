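Package: finpose
Title: Heatmap-Based Pose Tracking and Swim Kinematics for Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for markerless pose tracking of embryonic and
    larval zebrafish in single- and multiwell recordings, and for the downstream
    kinematic analysis of escape and visuomotor behavior. Keypoints along the
    rostral-caudal body axis are regressed as two-dimensional Gaussian heatmaps
    by a compact convolutional network built from slimmed inverted-bottleneck
    residual blocks operating at a single internal resolution (an isotropic
    macro-architecture with pixel unshuffle patchification); a hierarchical
    encoder-decoder variant is included for comparison. The package provides the
    full training recipe (AdamW, Xavier initialization with a zeroed final
    layer, gradient accumulation, label-consistent augmentation), parameter and
    theoretical-minimum memory-footprint accounting, a seeded synthetic-fish
    generator so every stage is testable without recordings, and kinematic
    readouts: per-frame speed, rostral-caudal bend angle, high-amplitude bend
    events, swim-bout segmentation, and stimulus-window summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo:
    Rcpp
Config/testthat/edition: 3
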