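Package: accessout
Title: Chromatin Accessibility Outlier Detection with a Negative Binomial
    Linear Autoencoder
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects chromatin-accessibility outliers from per-region
    ATAC-seq read counts using a PCA-initialised linear autoencoder with a
    negative binomial observation model. Includes a linear-time sorted-sweep
    read counter for non-overlapping peak sets, replication-rate filtering,
    median-of-ratios size factors, bounded dispersion maximum likelihood
    estimation, a two-sided negative binomial test with Benjamini-Yekutieli
    correction, an artificial-outlier injection benchmark (naive negative
    binomial and PCA baselines, precision-recall evaluation), functional
    annotation of accessible regions from histone ChIP-seq marks and gene
    models, Hi-C contact and activity-by-contact (ABC) scoring, and per-gene
    feature construction linking accessibility outliers to expression
    outliers. Synthetic fixture generators cover every input so the package
    tests offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    rtracklayer,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
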