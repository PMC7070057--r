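Package: hetlink
Title: Link Prediction on Heterogeneous Molecular Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for representing and completing heterogeneous molecular
    association networks that join miRNAs, lncRNAs, proteins, drugs and
    diseases through nine relation types. Every node is described by the
    concatenation of an attribute vector (3-mer sequence composition,
    reduced-alphabet protein 3-mers, MeSH-DAG disease semantic similarity,
    chemical fingerprints, unified to 64 dimensions by a sparse autoencoder)
    and a behavior vector (64-dimensional graph-factorization embedding
    trained by sequential stochastic gradient descent). Candidate edges of
    any relation type are scored with ensemble classifiers under balanced
    negative sampling, with cross-validation, feature-ablation,
    training-proportion, classifier-comparison, local-versus-global and
    leave-one-disease-out evaluation protocols, plus a seeded synthetic
    network generator with planted low-rank structure for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    ranger,
    e1071,
    glmnet,
    Biostrings,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
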