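Package: backsplicer
Title: Discovery and Quantification of Circular RNAs from Scrambled Exon Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and quantifies exonic circular RNAs in intron-poor
    eukaryotes from RNA-seq data. Builds a database of all intragenic
    exon-exon junction sequences, including scrambled-order (back-splice)
    junctions, using read-length-dependent flanks padded by tandem repeats
    that mimic rolling-circle reverse transcription; aligns reads to the
    database with an ungapped mismatch-bounded unique aligner; calls
    circular RNA candidates with predicted circle sizes; estimates circles
    per cell from junction read rates and per-cell mRNA copy numbers; and
    computes RNase R resistance (delta-Ct, delta-delta-Ct) and per-cell
    timecourse quantities from qPCR Ct tables. Includes a fully seeded
    synthetic-data generator (genomes, annotations, molecule pools,
    exonuclease treatment, reads with rolling-circle concatemers, Ct
    tables) with ground-truth tracking for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
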