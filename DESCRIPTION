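Package: sigscreen
Title: Ligand-Based Virtual High-Throughput Screening with Signature
    Descriptors and GA-SVM Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ligand-based virtual high-throughput screening (vHTS)
    pipeline for small-molecule inhibitor discovery.  Molecules are
    fragmented into canonical atomic Signature descriptors (rooted,
    bond-labelled subtrees at heights 0-2), assembled into an
    occurrence-count descriptor matrix, pre-filtered by principal
    component analysis, and modelled by a genetic-algorithm feature
    search wrapped around linear support vector machines (classification
    of active/inactive plus IC50 regression), scored by stratified
    cross-validation.  Candidate libraries are screened with the tied
    model ensemble under an overlap (applicability-domain) metric and
    staged selection criteria; plate-reader fluorescence data are
    reduced to percent inhibition and interpolated IC50 values, and
    validated compounds are folded back into the training set for
    retraining rounds.  Includes PAINS and near-duplicate structure
    filters and a synthetic-library generator with a planted
    substructure-activity rule for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
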