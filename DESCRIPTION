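Package: enrichscape
Title: Network-Based Transcriptional Landscape Mapping from Preranked
    Gene-Set Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds transcriptional-landscape networks from bulk RNA-seq
    count data. Provides a documented simplified differential-expression
    estimator (median-of-ratios normalization, Welch test on log2
    normalized counts, ridge shrinkage of log2 fold changes), a
    from-scratch preranked gene-set enrichment analysis with a
    permutation null, leading-edge extraction and Benjamini-Hochberg
    adjustment, construction of a thresholded gene-set overlap network,
    a Markov Cluster (MCL) implementation, projection of additional
    group comparisons onto a fixed network scaffold with themed
    directional summaries, and a ligand/receptor interactome overlay of
    gene-level significance classes. A negative-binomial synthetic-study
    generator with planted pathway signals makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
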