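Package: reguloncascade
Title: Multi-Omics Accounting of a Transcription-Factor Cascade in Meiosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates ChIP-seq binding, RNA-seq differential expression and
    ATAC-seq chromatin accessibility into the regulon accounting used to study
    the germline transcription factor ZFP541. Annotates binding peaks to gene
    promoters and bodies, calls differentially expressed genes with a
    median-of-ratios plus Welch-test engine, partitions DEGs into
    bound/unbound x up/down quadrants, overlaps binding with
    differential-accessibility calls, scans position weight matrices over
    accessible regions to nominate core transcription factors, and measures how
    much of the differential transcriptome a TF-target network covers. Ships a
    seeded multi-omics simulator with planted ground truth and a deterministic
    fixture whose marginal counts make every accounting statistic checkable
    exactly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
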