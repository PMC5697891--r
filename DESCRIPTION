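Package: splicecomb
Title: Combinatorial Splicing Regulation Analysis from Splice-Junction Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Junction-based quantification of alternative splicing (percent
    spliced in, PSI) and differential-splicing calls between wild-type and
    splicing-factor mutant samples; identification of conserved RNA-binding
    protein motifs in splice-proximal regions using a multi-species genome
    alignment; motif enrichment against PSI-matched controls, motif
    co-occurrence, inter-motif spacing and ordering conservation statistics;
    and multiplicative genetic-interaction scores from worm fitness assays.
    Includes a seeded synthetic-study generator (genome, annotation, junction
    tables, alignments with planted motifs, fitness plates) with a truth
    table, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
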