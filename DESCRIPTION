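Package: sigfuge
Title: Unsupervised Detection of Differential Isoform Usage from
    Per-Base RNA-Seq Coverage
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clusters RNA-seq samples at single gene loci by their
    per-base expression curves and attaches a simulation-based p-value
    for differential isoform usage.  At each locus, lowly expressed
    samples are filtered out, the remaining coverage curves are
    count-normalized and log-transformed, split into two groups by
    2-means clustering, and the tightness of the split (the 2-means
    cluster index) is compared against datasets drawn from a single
    Gaussian whose covariance eigenstructure is estimated from the
    data.  Includes coverage extraction from BAM alignments against
    union gene models, an exon-level (RPKM) variant of the analysis,
    a negative-binomial coverage simulator for two-isoform gene models
    with power-study drivers, Benjamini-Hochberg FDR control across
    loci, and expression-curve plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
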