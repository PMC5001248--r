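Package: lcpf
Title: Match-Point Graphs for Longest Common Subsequences and
    Reference-Based Compression via Longest Previous Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the longest common subsequence (LCS) of two
    sequences by enumerating single-symbol match points, indexing them
    with rank-compressed maximum tables, assembling a directed acyclic
    graph of immediate-predecessor relations, and extracting the LCS as
    a longest source-to-sink path.  The same machinery motivates a
    reference-based lossless codec for genome resequencing data: the
    longest-previous-factor (LPF/POS) arrays over the concatenation of a
    reference and a target are scanned left to right, encoding factors
    of length at least k as fixed-width 12-byte triples and shorter
    stretches as literal bytes, with optional payload/case-bitstring
    decomposition and built-in post-compression.  Includes a seeded
    mutation simulator for reference/target pairs, FASTA input/output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
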