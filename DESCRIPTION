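Package: bxdseeker
Title: Discovery of Benzoxazinoid-Degradation Gene Clusters by Comparative Genomics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for associating bacterial genotypes with a binary
    degradation phenotype and for locating the responsible gene cluster.
    Implements a canonical-kmer genotype-phenotype association pipeline
    (presence/absence scoring, greedy sequence clustering at an identity
    threshold, Fisher's exact tests with Benjamini-Hochberg correction),
    gene-family presence/absence association, a lightweight differential
    expression stage, three-way evidence intersection, adjacency-based
    gene-cluster calling with systematic gene naming, cluster-architecture
    typing, and protein best-hit homology screening. Ships a synthetic
    genome-set generator with a planted gene cluster and matching
    phenotyping assay tables for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
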