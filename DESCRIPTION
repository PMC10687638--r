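Package: homeoDivergence
Title: Expression Divergence of Retained Homeolog Triplets Under Cold Stress
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis of expression divergence among triplicated homeologs in
    hexaploid Camelina sativa under cold stress. Implements FPKM/TPM
    quantification with TMM between-sample normalization, a two-group
    negative-binomial exact test with common-dispersion estimation,
    control-condition dominance classification of syntelog triplets
    (Class 1/2/3), cold-inducibility typing (Type 1/2/3) with rank-based
    divergence flags, thresholded Pearson coexpression networks with Leiden
    modules, hypergeometric term enrichment, and a negative-binomial
    simulator with planted truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR
biocViews: Transcriptomics, DifferentialExpression, GeneExpression,
    Network, RNASeq, Normalization
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
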