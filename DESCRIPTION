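Package: teexon
Title: Transposable-Element Exonization Analysis of Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies exons and transcripts of assembled transcriptomes as
    transposable-element (TE) derived by genomic overlap with RepeatMasker
    annotation, quantifies the enrichment of TE-derived first exons and
    transcription start sites, matches records between assemblies with a
    bounded coordinate tolerance, normalizes per-family TE contributions by
    genomic background abundance with a chi-square heterogeneity test and
    millidiv-based age ranking, correlates expression-binned epigenetic
    signal (histone marks, DNaseI hypersensitivity, CAGE) with exon
    expression via Pearson's r and its Student-t approximation, and tests
    differential expression between two conditions with BH-FDR q-values.
    Includes a ground-truth-labelled synthetic data generator so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
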