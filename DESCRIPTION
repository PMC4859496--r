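Package: ReadBurden
Title: Rare-Variant Burden Testing from Sequencing Reads Without Calling
    Genotypes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Likelihood-based rare-variant burden testing for case-control
    sequencing studies that models per-locus read counts directly instead of
    called genotypes, so that systematic differences in depth and base-calling
    error rate between cases and controls do not confound the test. Provides
    the score statistic on posterior minor-allele dosages under a restricted
    EM fit, a derivative-based screening rule for unknown variant locations,
    an adjusted empirical-Bayes estimator of locus-specific error rates, a
    read-based quality-control statistic, a monomorphic-bootstrap significance
    procedure with isotonic deconvolution of the true-variant allele-frequency
    distribution and a sequential stopping rule, genotype-calling and dosage
    comparator tests, and a simulator of case-control read data with
    differential sequencing quality.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Genetics, Sequencing, SNP, StatisticalMethod, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
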