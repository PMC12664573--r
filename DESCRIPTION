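Package: ksmofinder
Title: Kinase-Substrate-Motif Prediction from a Phosphorylation Knowledge Graph
Version: 0.1.0
Authors@R:
    person("KSMoFinder", "Developers", email = "ksmofinder@example.org",
           role = c("aut", "cre"))
Description: Builds a phosphorylation knowledge graph over kinases, substrate
    proteins and 9-mer phosphosite motifs, learns knowledge-graph embeddings
    (TransE, DistMult, ComplEx) with pairwise hinge loss and MRR-based early
    stopping, constructs a supervised classification dataset with
    biologically motivated negative sampling from interaction and kinase
    specificity data, and trains a bilinear neural classifier that scores
    kinase-substrate_motif phosphorylation events. Includes a
    link-prediction evaluation harness (ROC-AUC, PR-AUC, bootstrap
    confidence intervals, easy-test filtering) and a seeded synthetic-world
    generator so every pipeline stage is testable without external
    database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
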