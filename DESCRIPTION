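Package: annScreen
Title: Stepwise Artificial Neural Network Screening and Network Growth for
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ranks every probe of a gene expression matrix by how well a
    minimal multilayer perceptron (one input, two sigmoid hidden nodes,
    one sigmoid output, online backpropagation with momentum) trained on
    that single probe predicts a target gene's expression, under Monte
    Carlo cross-validation with 60/20/20 train/test/validation splits.
    Top-ranked genes are recursively re-screened to grow an interaction
    network, and cross-run gene frequencies are tabulated. Includes
    readers for tab-delimited probe-by-sample matrices with sample
    metadata and probe annotation, an estrogen-receptor-status cohort
    filter, and a synthetic hub-partner expression simulator with planted
    correlation structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    igraph,
    ggplot2,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'ann.R'
    'data_io.R'
    'screen.R'
    'network.R'
    'synthetic.R'
    'pipeline.R'
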