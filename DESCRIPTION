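Package: rna2dalign
Title: Multiple RNA Alignment from Known Secondary Structures via a
    Pseudo-Amino-Acid Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Aligns sets of RNA molecules with known secondary structures by
    reversibly re-encoding each (nucleotide, dot-bracket symbol) pair -- or the
    structure symbols alone -- as letters of the 20-letter amino-acid alphabet,
    aligning the resulting pseudo-amino-acid sequences with a substitution
    matrix generated from eight interpretable scoring parameters, and decoding
    the result back to gapped RNA sequences plus structures. Handles
    pseudoknots (canonical bracket-page notation, demotion of higher-order
    pages), modified nucleotides (stripped before encoding, restored after
    alignment), and provides a built-in deterministic progressive aligner as
    well as an adapter for an external protein aligner. Also includes the
    evaluation stack (sum-of-pairs score, positive predictive value, consensus
    structure and structural edit distance), a coordinate-search optimizer for
    the matrix parameters, and a seeded synthetic RNA-family generator.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
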