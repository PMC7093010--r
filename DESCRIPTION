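Package: phenomtl
Title: Multitask Convolutional Networks for Top-View Rosette Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint estimation of leaf count, projected leaf area (PLA) and
    binary genotype class from top-view images of rosette plants (e.g.
    Arabidopsis thaliana) with a hard-parameter-sharing multitask
    convolutional network trained under a label-masked loss, so that images
    lacking an annotation for one task still contribute to the others.
    Includes a seeded synthetic rosette generator (phyllotactic leaf
    placement, genotype-dependent shape and hue, growth time series) that
    provides exact ground truth for all three traits; the CVPPP leaf-count
    metric suite (DiC, absolute DiC, agreement, MSE, R squared); a
    bootstrapped paired t-test; sliding black-window occlusion sensitivity
    maps; and reproducible experiment drivers for multitask versus
    single-task comparisons and count-annotation reduction studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    grDevices,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
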