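Package: motifpair
Title: Exact Planted (l,d) DNA Motif Search via l-mer Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Exact pattern-driven search for planted (l,d) DNA motifs, the
    model behind transcription-factor binding-site discovery benchmarks.
    Pairs of l-mers drawn from the input sequences restrict the candidate
    space to the intersection of their radius-d Hamming balls, which is
    enumerated deterministically and verified against filtered sequence
    windows. Includes closed-form candidate-count and mapping-relation
    machinery, a 2-bit-encoded table-driven Hamming distance, a planted
    instance simulator with ground-truth manifests, motif ranking by
    consensus score and relative entropy, nucleotide-level correlation
    coefficient evaluation, brute-force oracles for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Biostrings,
    optparse,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
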