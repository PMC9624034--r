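Package: lncmeth
Title: Genome-Wide Screen for DNA-Methylation-Driven Long Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying long noncoding RNAs
    (lncRNAs) whose expression changes in tumors are linked to aberrant
    promoter DNA methylation. Reannotates 450K-style CpG array probes to
    strand-aware lncRNA promoter windows, screens probes and genes for
    differential methylation and expression with rank tests and
    Benjamini-Hochberg control, detects differentially methylated regions by
    bump hunting with label-permutation resampling, integrates both screens
    into methylation-driven (CpG, lncRNA) pairs with Spearman correlation
    annotation, quantifies clone-level methylation from bisulfite sequencing
    PCR (BSP) with conversion-rate QC, selects diagnostic cut-offs by
    Youden-index ROC analysis, and stratifies survival with Kaplan-Meier
    curves and log-rank tests. A synthetic-data module generates every input
    with planted ground truth so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
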