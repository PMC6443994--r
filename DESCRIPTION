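Package: wdinet
Title: Weighted Diverse Interaction Networks for Cross-Tissue
    Differential Co-Expression Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds weighted diverse interaction networks (WDINs) from
    two-condition expression data over a background interactome,
    prioritizes genes and interactions by weighted random walk with
    restart from a seed set, compares networks across tissues with an
    edge-overlap S-score, extracts clustering-coefficient-maximizing
    core modules from the prioritized edges, merges tissue core modules
    into a merged core module via a per-interaction Jaccard criterion,
    and classifies merged-module edges as tissue-specific, differential,
    or common.  Ships a synthetic-data generator that plants
    differentially correlated gene pairs on a scaffold network so every
    pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, GeneExpression,
    DifferentialExpression, Network, SystemsBiology
RoxygenNote: 7.3.3
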