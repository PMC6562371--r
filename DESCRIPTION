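Package: tessmut
Title: Tessellation-Based Four-Body Potentials and Computational Mutagenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delaunay tessellation of C-alpha protein models, a four-body
    knowledge-based statistical potential over residue quadruplets, and a
    computational-mutagenesis workflow that scores single-residue variants by
    the structural perturbation they induce (residual scores and
    environmental-perturbation profiles). Includes feature-vector assembly for
    variant-effect prediction, random-forest classification and bagged
    regression trees with correlation-based feature selection,
    cross-validation, permutation controls, learning curves, and stratified
    performance reporting, plus a synthetic-data generator of protein-like
    C-alpha chains and planted-signal fitness tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    ranger,
    rpart,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
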