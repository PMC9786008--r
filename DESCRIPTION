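Package: moladr
Title: Dual-Channel Molecular Encoding for Multi-Label Adverse Drug Reaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts adverse drug reaction (ADR) classes from chemical
    structure alone, as a multi-label classification problem. Each drug is
    encoded through two channels: a graph isomorphism network (GIN) with
    linear message passing and max-pool readout over the molecular graph
    (atoms carry atomic number and chirality, bonds carry bond type and
    direction), and a multi-head self-attention encoder over the 256-digit
    hexadecimal rendering of the 1024-bit FP2 path fingerprint. Three
    objective-tagged graph embeddings (Infomax, Edge, Context) and the
    sequence feature are concatenated and fed to a sigmoid multi-label
    head trained with binary cross-entropy and Adam. Includes macro-averaged
    multi-label evaluation (accuracy, precision, recall, ROC-AUC, PR-AUC),
    holdout/k-fold/jackknife protocols, dataset label statistics, a
    planted-substructure synthetic dataset generator, and a command-line
    harness. Chemistry input/output is delegated to Open Babel via
    ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
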