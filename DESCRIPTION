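Package: mcdetect
Title: Microcalcification Cluster Detection with Sparse Representation and Twin Support Vector Machines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and classification of clustered microcalcifications in
    mammogram-like images. Test patches are sparsely coded against a labelled
    vocabulary of training patches by l1-regularized least squares (coordinate
    descent with a duality-gap certificate), then classified either by
    class-restricted reconstruction residuals (sparse representation
    classification) or by twin support vector machines trained on the sparse
    codes (two box-constrained dual quadratic programs, linear or RBF kernel).
    Includes a DDSM-like phantom generator with ground-truth spot annotations,
    a sliding-window patch pipeline, ROC/Az evaluation with stratified
    cross-validation and repeated-subsampling stability experiments, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    png,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
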