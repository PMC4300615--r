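Package: refusion
Title: Fusion Transcript Detection from Split and Discordant RNA-seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects gene-fusion transcripts from paired-end RNA-seq
    alignments. Candidate breakpoints are called from chimeric, partially
    aligned (soft-clipped) and discordant read pairs under a tiered relaxed
    scan; abnormal read pairs anchored around each grouped breakpoint are
    assembled regionally with an internal de Bruijn assembler; contigs are
    re-aligned to the genome by seed-and-extend, chained into best and
    second-best concatenated paths, and junctions hitting two different genes
    are quantified by spanning and encompassing read support, scored
    (Spanning Score and alignment score Q), filtered, ranked, merged by
    isoform and classified (Intra/Inter, in-frame/out-of-frame). A
    deterministic simulator of toy genomes, gene models, planted fusions,
    paired reads and mapper-like SAM output makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    parallel,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
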