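Package: shootseg
Title: Patch-Based U-Net Segmentation and Phenotyping of Greenhouse Plant Shoots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated segmentation and quantitative phenotyping of RGB images
    of greenhouse-grown plant shoots. Implements a batch-normalized
    encoder-decoder U-net with 7x7 convolutions operating on non-overlapping
    256x256 patches, the full pad/tile/predict/reassemble/threshold/clean
    inference chain for images of arbitrary resolution, Dice and binary
    cross-entropy evaluation, a 35-trait shoot quantification stage (area,
    bounding box, convex hull and color statistics), a shallow pixel-neighborhood
    neural-network baseline, and a seeded synthetic greenhouse-scene generator
    with pixel-exact ground-truth masks so that the whole pipeline is trainable
    and testable without external data. The convolutional engine (convolution,
    transpose convolution, batch normalization, Adam optimization with a
    reduce-on-plateau learning-rate schedule) is implemented in C++ via
    RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    png,
    tiff,
    jpeg,
    grDevices,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
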