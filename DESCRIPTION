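Package: pgxpanel
Title: Targeted Pharmacogene Panel Sequencing Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for targeted pharmacogene capture panels:
    panel and evaluation-interval bookkeeping, read-level and coverage
    quality control with sample-exclusion rules, quality-threshold diploid
    genotype calling at known pharmacogene sites, automated promoter (TA)n
    repeat genotyping (UGT1A1*28-style) from spanning reads, read-depth
    copy-number calling for CYP2D6 against a two-copy reference panel,
    variant functional/frequency/deleteriousness classification, CYP2D6
    activity-score phenotype prediction, and concordance assessment against
    orthogonal genotyping. Ships a seeded read simulator emitting SAM/FASTQ
    with full ground truth (copy-number states, repeat genotypes, SNVs,
    GC bias, batch effects) so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tibble,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    jsonlite,
    optparse
Config/testthat/edition: 3
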