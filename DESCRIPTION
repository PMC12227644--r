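Package: grffuse
Title: Annotation and Mechanistic Classification of RAS-GEF Gene Fusions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns raw RNA-seq fusion calls involving the RAS guanine
    exchange factors RASGRF1 and RASGRF2 into a curated, structurally
    annotated, mechanistically classified fusion cohort. Builds chimeric
    transcripts from GTF gene models and genome sequence, determines
    reading-frame status by codon phase arithmetic, maps retention and loss
    of the PH1, DH, PH2, REM and CDC25 domains onto the chimeric protein,
    predicts transmembrane topology of 5' fusion partners with a
    Kyte-Doolittle sliding-window hydropathy model, applies a candidate
    functional filtering funnel (read support, intact CDC25 domain, coding
    exonic endpoints, reading frame), assigns each fusion a
    transforming-potential class, and aggregates cohorts into per-gene,
    per-partner and demographic summaries. Includes a seeded synthetic-data
    generator that emits genomes, gene models, fusion calls and subject
    tables with known truth, and a transcribed 40-fusion reference cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
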