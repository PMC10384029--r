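Package: cubkit
Title: Codon Usage Bias Analysis of Protein-Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing synonymous codon usage bias in sets of
    protein-coding sequences. Reads coding-sequence FASTA files, applies
    quality filters (frame, length, start/stop codons, internal stops,
    ambiguous bases, duplicates), and computes per-gene nucleotide
    composition (GC, GC1-GC3, GC12, GC3s, A3/T3/C3/G3), the effective
    number of codons (ENc) in the codon-family pseudocount formulation
    together with Wright's expected-ENc curve and the ENc ratio, relative
    synonymous codon usage (RSCU) with representation classes, the codon
    adaptation index (CAI), Gravy and aromaticity, parity-rule-2 (PR2)
    coordinates, the P2 translational-selection index, the GC12-on-GC3
    neutrality regression, correspondence analysis of the gene-by-codon
    RSCU matrix, putative optimal codon identification, and correlation
    panels. Includes a seeded synthetic coding-sequence generator with
    controllable mutational bias (GC3 target) and selection-like codon
    preference so every stage of the pipeline can be validated against
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite
Config/testthat/edition: 3
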