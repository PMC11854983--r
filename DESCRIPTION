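Package: mitocub
Title: Mitochondrial Genome Composition and Codon Usage Bias Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for analysing annotated animal mitochondrial
    genomes: GenBank flat-file reading and writing, extraction of in-frame
    protein-coding genes with incomplete-stop handling, base composition and
    AT/GC strand skews, codon counting and relative synonymous codon usage
    (RSCU), positional GC content (GC1/GC2/GC3/GC12/GC3s), Wright's effective
    number of codons with the expected ENC-GC3s curve, and the GC12-on-GC3
    neutrality regression. Includes a seeded generator of synthetic annotated
    mitogenomes (beetle-like 37-feature gene order, strand assignment, gene
    overlaps, incomplete stop codons, tunable AT content and synonymous-codon
    bias) so every stage of the pipeline is testable without downloads, plus
    report writers for single-genome and multi-species comparative analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
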