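Package: isoforge
Title: Long-Read Transcriptome Triage, Mis-Mapping Testing, Fusion and
    Splicing Analysis with Planted Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing full-length transcript sequencing of plant
    transcriptomes from single-molecule long reads. Implements the triage of
    raw reads into full-length and non-full-length signal classes, a
    binomial/Gaussian mismatch-rate test for detecting mis-mapped noisy
    alignments, split-alignment fusion-transcript calling with paired-read
    validation, transcript-versus-annotation class codes, alternative-splicing
    event typing (intron retention, alternative donor/acceptor, exon skipping)
    with short-read support rules, and the downstream expression and long
    non-coding RNA filter cascades. A synthetic-data generator builds toy
    genomes, gene models, isoforms with planted splicing events, error-bearing
    long reads and short-read support tables with complete ground truth, so
    every stage can be exercised end to end against a known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
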