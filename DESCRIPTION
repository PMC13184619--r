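Package: teit
Title: Detection, Quantification and Clinical Scoring of
    Transposable-Element-Initiated Transcripts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transcripts that initiate inside annotated
    transposable elements (TEs) from assembled short-read RNA-seq
    transcriptomes. A convolutional model trained on cap-based TSS
    labels predicts the transcription start site of each assembled
    transcript from DNA sequence plus RNA-seq coverage; predicted
    starts are corrected across samples with a support-weighted score,
    intersected with TE annotation, and merged into a reference-guided
    catalogue. The package quantifies first-exon junction support and
    family-level promoter activity, classifies transcripts
    structurally and by coding consequence, and computes
    tumour-specificity, enrichment, and clinical-association
    statistics. A seeded synthetic-cohort generator provides ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    survival,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
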