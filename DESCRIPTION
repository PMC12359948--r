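Package: molgraphnn
Title: Graph Neural Networks on 3D-Optimised Molecular Graphs for Binary
    Property Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts SMILES strings into standardised, three-dimensionally
    optimised molecular graphs carrying geometry- and charge-derived features
    (MMFF94 bond lengths, Gasteiger partial charges, valence and ring
    descriptors), and trains four message-passing neural network
    architectures (GCN, GAT, GraphSAGE, GIN) for binary molecular property
    classification such as drug-induced liver injury. Training follows a
    stratified nested cross-validation protocol with combined-rank
    hyperparameter selection, seed reinitialisation, and sequential warm
    starts stopped by a Wilcoxon rank-sum test with Sidak correction.
    Chemistry primitives (SMILES parsing, neutralisation, 3D embedding,
    MMFF94 minimisation, partial charges) are delegated to OpenBabel via
    ChemmineOB; the network layers, training protocol and statistics are
    implemented in R.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
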