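Package: daavf
Title: Deep Archetypal Analysis of Visual Fields with Class-Balanced Bagging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Convex-hull dictionary learning for fixed-length clinical
    measurement vectors such as Humphrey 30-2 visual fields. Implements
    single-layer archetypal analysis by block-coordinate descent under
    simplex constraints, layered (deep) archetypal factorization with
    composed dictionaries and correlation-based atom pruning, simplex
    projection of new samples onto a learned dictionary, a class-balanced
    bagging classifier built from small feed-forward networks trained with
    Adam, subject-grouped stratified cross-validation with ROC/AUC
    evaluation, a synthetic visual-field generator with planted defect
    archetypes, and a command-line interface tying the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
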