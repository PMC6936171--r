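Package: dielsplice
Title: Diel Alternative-Splicing Dynamics of Plant Clock Genes from
    Fragment-Analysis Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for field time courses of alternative
    splicing (AS) in plant circadian-clock genes measured by
    high-resolution RT-PCR fragment analysis. Annotates AS events
    (intron retention, exon skipping, alternative splice sites,
    alternative exons) on gene models and classifies their transcript
    and protein consequences (premature termination codons vs in-frame
    deletions); sizes capillary-electrophoresis peaks against a ladder
    and converts them to reference-gene-normalized isoform abundances;
    normalizes field sampling times to zeitgeber time under seasonal
    photoperiods; estimates diel peak phases from LOESS fits; computes
    log(AS/FS) splicing-ratio rhythms and their fold range; and
    regresses splicing ratios on ambient temperature. A seeded
    synthetic-study generator emulates the sampling design so every
    stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
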