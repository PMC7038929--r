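Package: chimerascope
Title: Post-Detection Analysis of Chimeric RNA Call Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of chimeric RNA (fusion
    transcript) call sets produced by split-read fusion callers on bulk
    RNA-seq cohorts. Implements junction classification against a gene
    annotation (exon-end versus mid-exon breakpoints; read-through versus
    intra- and inter-chromosomal gene pairs; reading-frame and canonical
    splice-motif assessment), a staged false-positive filtering ladder
    (prediction-score, junction-sequence identity against a reference
    transcriptome, chimera-to-parent expression ratio, M/M removal, global
    and tissue-aware recurrence), binary presence/absence profiling with
    simple-matching-coefficient comparison to parental gene expression,
    in-silico chimeric peptide prediction (flank assembly, three-frame
    translation, tryptic digestion, junction-spanning retention, PSM
    filtering and reference-proteome screening), matching against cancer
    fusion databases at gene-pair and exact-breakpoint resolution, and
    normal-baseline filtering of cancer call sets. A fully self-contained
    synthetic-data generator with planted ground truth supports end-to-end
    testing without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
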