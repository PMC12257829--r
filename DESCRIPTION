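Package: strongmark
Title: Identify Weak and Strongly Unique Canonical k-mers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marks, within a set of distinct canonical DNA k-mers, every k-mer
    that has a canonical-Hamming-distance-1 neighbour in the same set ("weak"
    k-mers), using a recursive 4-way comparison over the sorted expanded array
    (FourWay), a hybrid that switches to bit-parallel pairwise testing on short
    intervals (FourWay+Pairwise), and a prefix-bucketing algorithm with a
    section swap (Quarter). Combined with occurrence counts this classifies
    k-mers as strongly unique, weakly unique or non-unique. Includes the two
    naive baseline algorithms as oracles, generators for extremal (all-weak,
    all-strong) and random datasets, chunked low-memory construction, and
    block-wise genomic uniqueness profiles. k-mer codes are 2k-bit integers
    handled exactly for k up to 31 via compiled 64-bit arithmetic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
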