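Package: combonet
Title: Drug Combination Prediction by Joint Heterogeneous Network
    Embedding and Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether two drugs combine synergistically or
    antagonistically from a heterogeneous network of drug-drug similarity
    (ATC-code or chemical-fingerprint Jaccard), drug-target incidence and
    protein-protein interactions.  Drug embeddings are learned by symmetric
    nonnegative matrix factorization of the similarity network and
    Laplacian-regularized nonnegative factorization of the drug-target
    network, coupled to a hinge-loss kernel classifier on drug pairs so
    that the representation is shaped by the classification task
    (semi-supervised joint learning).  Includes readers and writers for
    the tabular network formats, a planted-structure synthetic-data
    generator, cross-validated evaluation metrics, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    e1071,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
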