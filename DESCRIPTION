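Package: MicroNetRMT
Title: Abundant and Rare Microbial Co-Occurrence Networks via Random
    Matrix Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the comparative network analysis of abundant and
    rare soil microbial communities across ecological gradients such as
    successional stages. Implements abundance-class partitioning of ASV
    tables (abundant > 0.1%, rare < 0.01% mean relative abundance) with
    prevalence filtering, alpha- and beta-diversity statistics (Chao1,
    Shannon, Bray-Curtis, PCoA, ANOSIM, rank-sum group tests), random
    matrix theory (RMT) based selection of the correlation threshold for
    co-occurrence network construction through the transition of the
    nearest-neighbour eigenvalue spacing distribution from
    Gaussian-orthogonal-ensemble to Poisson statistics, full network
    topology characterization against degree-preserving random-graph
    null ensembles, Zi-Pi topological role classification of putative
    keystone taxa, and Mantel / partial Mantel tests linking community
    structure to environmental drivers. A synthetic community generator
    with planted correlation modules provides ground-truth benchmarks
    for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    vegan,
    jsonlite,
    biomformat,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Microbiome, Network, Metagenomics, Software
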