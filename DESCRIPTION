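Package: memclust
Title: Greedy Incremental Clustering of Long Nucleotide Sequences with
    Sparse Suffix Arrays and Maximal Exact Matches
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dereplication of complete and draft genomes by greedy
    incremental clustering. Sequences are sorted long-to-short and each
    query is compared against earlier representatives through maximal
    exact matches (MEMs) enumerated from a sparse suffix array over the
    representative text. Raw MEMs are refined to disjoint segments,
    extended under an x-drop score scheme (ungapped or gapped), and
    summarised as an extended-MEM identity (matched bases divided by
    query length). Includes a block-partitioned clustering engine with a
    deterministic parallel-execution contract, a synthetic-genome
    benchmark generator with known redundancy structure, and a command
    line interface for clustering, MEM scanning, and fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
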