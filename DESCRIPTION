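Package: winchip
Title: Window-Based Differential ChIP-seq Enrichment and Bivalent Promoter
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Sliding-window analysis of histone-modification ChIP-seq data:
    genome-grid window counting with global-background filtering and
    merge-with-split region calling; loess MA normalization of
    immunoprecipitation-efficiency biases; negative-binomial per-window
    differential tests with trended, empirical-Bayes-shrunk dispersions;
    Simes combination of window p-values at promoters with
    Benjamini-Hochberg correction; promoter enrichment classification from
    bimodal abundance densities with CpG density annotation; bivalency and
    set-overlap statistics; RPKM coverage tracks; and a seeded synthetic
    read generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: ChIPSeq, DifferentialPeakCalling, Epigenetics, Normalization,
    Sequencing
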