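Package: epimutacc
Title: Epimutation Accumulation Analysis for Multigenerational C. elegans Lines
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing heritable epimutations in mutation-accumulation
    lines of Caenorhabditis elegans sampled every two generations under
    genotoxic stress. Implements residual Z-score epimutation calling on
    locus-by-sample count matrices (loess or linear regression of each
    generation against the founder), cutoff calibration against an
    independent-call null, run detection with missing-generation bridging,
    Kaplan-Meier/log-rank duration statistics, Jonckheere-Terpstra ordered
    trend tests, tRNA-derived 3' half fragment quantification and
    mismatch-tolerant target search, mutation-fixation filtering of
    per-generation variant calls, and a gene-centric Fisher-exact association
    battery linking expression changes to small-RNA epimutations. A synthetic
    data generator with recoverable ground truth emulates the full study
    design for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epigenetics, GeneExpression, SmallRNA, Sequencing, Software
RoxygenNote: 7.3.3
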