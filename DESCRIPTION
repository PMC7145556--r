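Package: riboQueue
Title: Ribosome Queuing Analysis at Stop Codons from Ribo-Seq Coverage
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantifies ribosome queuing upstream of stop codons in ribosome
    profiling (Ribo-Seq) data. Provides read-length-specific P-site
    assignment, reads-per-million normalisation and replicate pooling for
    transcript-coordinate footprint alignments (with an optional
    genome-to-transcript projector for GFF3-annotated genomes), stop-codon
    anchored metagene profiles with wave-period estimation, the per-ORF
    C-terminal ribosome queuing metric with Z-score selection, pLogo-style
    positional amino-acid enrichment with exact binomial log10-odds and
    Bonferroni significance lines, stop-codon context and identity tests,
    3'UTR readthrough diagnostics, and a seeded synthetic footprint
    generator that emulates a wild-type versus termination-defective
    experimental design for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
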