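Package: panomap
Title: Multi-Omic Sample Maps with Density Clustering and Contribution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates same-sample measurements of gene expression, DNA
    methylation, copy number and microRNA abundance into a two-dimensional
    sample map. Each data type is normalized by its platform-appropriate
    transform, reduced by principal component analysis, variance-balanced,
    and concatenated; the joint space is embedded by multi-restart
    t-distributed stochastic neighbour embedding selected by lowest
    Kullback-Leibler divergence. Downstream tools provide density-based
    clustering with silhouette-driven radius selection under a noise cap,
    hypergeometric cluster-label enrichment, detection of samples falling
    outside their tissue-of-origin cluster, per-sample neighbourhood-overlap
    contribution analysis across all data-type combinations, rank-based
    local-similarity scores between maps, survival comparisons, gene-set
    enrichment and thresholded co-expression networks. A synthetic multi-omic
    cohort generator with planted ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    cluster,
    survival,
    igraph,
    limma,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'cluster.R'
    'contribution.R'
    'integrate.R'
    'mapeval.R'
    'omics-io.R'
    'outcomes.R'
    'panomap-package.R'
    'synthdata.R'
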