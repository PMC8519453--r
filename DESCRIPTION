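Package: embednet
Title: Biomedical Word-Embedding Networks as Priors for Graph-Convolutional Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A text-mining-to-networks pipeline for systems biology. Normalizes a
    biomedical corpus with dictionary-based synonym substitution, trains skip-gram
    word embeddings, validates entity-pair cosine similarities against knowledgebase
    group structure (pathway co-membership, protein-protein interactions, shared
    drug targets), extracts thresholded gene-gene similarity networks together with
    random control networks, and evaluates the networks as structural priors for a
    Chebyshev spectral graph-convolutional classifier on gene expression data under
    cross-validation. Ships synthetic-data generators that emulate the statistical
    structure of a literature corpus and of graph-smooth expression cohorts so the
    whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    igraph,
    minpack.lm,
    limma,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
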