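Package: ionprior
Title: Consensus Variant Calling and Tiered Prioritization for an
    Inherited Optic Neuropathy Gene Panel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the molecular-diagnosis computation of a targeted
    22-gene inherited optic neuropathy (ION) panel: multi-caller consensus
    variant calling over normalized, decomposed alleles; a tiered
    causative-variant prioritization cascade with mode-specific minor
    allele frequency thresholds, biallelic (compound-heterozygote)
    detection and pedigree segregation checks; per-base panel coverage QC
    with Sanger-backfill region reporting; and cohort-level
    diagnostic-yield summarization. A fully specified synthetic-cohort
    generator (toy panel genome, noisy per-caller VCFs, pedigrees, truth
    tables) makes every pipeline stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
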