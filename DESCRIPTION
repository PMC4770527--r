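Package: epityper
Title: DNA Methylation Epityping of Breast Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide DNA methylation epityping of tumor cohorts profiled on
    Illumina 450K-style arrays. Converts signal intensities to beta values with
    detection-p and bead-count masking, corrects Infinium I/II assay bias by
    per-sample peak normalization, selects CpG sites with tumor-specific
    methylation against a normal cohort, discovers methylation subtypes
    (epitypes) by bootstrap consensus clustering, classifies new samples by
    correlation to epitype centroids, extracts epitype-specific hyper- and
    hypomethylation patterns, integrates methylation with gene expression
    (including promoter methylation calling for candidate driver genes),
    annotates CpG sites with genomic context (chromatin states, repeats,
    subtelomeres), summarizes copy-number and mutation data, and provides the
    association and survival statistics used to characterize epitypes. A
    synthetic cohort generator with planted ground truth makes the whole
    pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    survival,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    rtracklayer
Config/testthat/edition: 3
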