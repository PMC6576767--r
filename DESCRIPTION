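Package: langdx
Title: Language-Based Prediction of Medical Conditions from Patient Social-Media Posts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Links per-patient social-media language to binary medical-condition
    labels. Encodes each participant's posts as topic-usage scores from a Latent
    Dirichlet Allocation model plus family-wise-error-selected unigram/bigram
    frequencies; compares language, demographics, and AUC-weighted ensemble
    classifiers by stratified cross-validated AUC with Monte-Carlo permutation
    tests and Benjamini-Hochberg false-discovery control; and identifies
    per-topic condition markers with quartile risk ratios and bootstrap
    confidence intervals. Includes a synthetic cohort generator with known
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    glmnet,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ranger,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
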