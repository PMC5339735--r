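Package: epirobust
Title: Replicate Variability and Differential Enrichment of Epigenomic Marks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools to quantify the robustness of epigenomic modifications
    across biological replicates. Implements a tile-based ChIP-seq workflow
    (fragment-center approximation, Poisson sliding-window domain calling,
    uniform tiling at 500 and 1,000 bp, count thresholding against input) with
    per-tile negative-binomial GLM likelihood-ratio testing under shared or
    group-specific dispersion, and a methylation-array workflow (probe
    filtering, dasen-style two-stratum quantile normalization, M-values,
    empirical-Bayes moderated t). The core statistics are the squared
    coefficient of variation of normalized tile counts and the replicate
    variance of M-values, compared between conditions by Wilcoxon rank-sum
    tests and stratified by genomic feature, chromatin bivalency and
    differentiation dynamics. Includes seeded synthetic-data generators with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    BiocGenerics,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    edgeR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
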