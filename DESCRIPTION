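Package: epiwindows
Title: Windowed Multi-Omic Differential Analysis of the Oocyte Epigenome
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrative window-based analysis of H3K4me3 ChIP-seq,
    whole-genome bisulfite methylation and gene expression in growing
    oocytes, built around three callers: an empirical-Bayes moderated
    t-test over 5 kb running windows of enrichment-normalized RPKM, a
    binomial logistic-regression test over 100-CpG windows with an
    absolute percent-methylation filter, and a simplified
    negative-binomial Wald test for differential expression. Adds
    promoter chromatin-state classification from H3K27ac/H3K27me3/FPKM,
    dinucleotide composition scoring of window sets against genome
    background, cross-layer overlap enrichment statistics, and a
    seeded synthetic oocyte-epigenome generator with planted ground
    truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    limma,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
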