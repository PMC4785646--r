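Package: tRFspace
Title: Genomic Ambiguity Profiling for tRNA-Derived Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding whether candidate tRNA-derived fragments
    (tRFs) in small RNA sequencing data are genuinely tRNA-specific.
    Constructs mature tRNA sequences from genomic annotation (intron
    splicing, strand resolution, non-templated CCA addition), profiles
    the exact genomic occurrences of mature-tRNA k-mers inside versus
    outside the annotated tRNA loci ("tRNA space"), quantifies cross-talk
    with tRNA-lookalike loci and short RepeatMasker tRNA segments, and
    classifies small RNA reads exactly onto mature tRNAs with fragment
    types (5'-tRF, 5'-half, i-tRF, 3'-half, 3'-tRF) and an
    exclusive/ambiguous genomic-origin label. Includes a synthetic genome
    and read simulator with planted decoy features and exhaustive ground
    truth, plus naive brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
biocViews: Sequencing, SmallRNA, Transcription, Annotation, Alignment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
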