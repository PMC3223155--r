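Package: markovbin
Title: Composition-Based Metagenomic Sequence Classification with
    Fixed-Order Markov Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Assigns metagenomic reads and contigs to source genomes by
    sequence composition. Each reference genome is summarised as a k-th
    order Markov model whose transition probabilities are stored as a
    negative-log cost vector of length 4^(k+1); query sequences are
    vectorized into (k+1)-mer transition counts and scored against every
    genome at once by a dense matrix product, with a constant penalty for
    transitions never observed in a genome. The minimum-score genome is
    reported together with its taxonomic lineage. Includes a reference
    database container with incremental extension, rank-level accuracy
    evaluation, community composition profiles, a seeded Markov-chain
    genome and read simulator for benchmarking, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
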