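# The two naive baseline algorithms. They define the weak set in two
# independent ways and serve as ground-truth oracles for the fast
# algorithms (and as runnable baselines).

#' Weak k-mers by full pairwise comparison
#'
#' Tests all `n(n-1)/2` unordered pairs of canonical codes with the
#' bit-parallel canonical-distance-at-most-1 test and marks both members of
#' every passing pair. Quadratic; intended as an oracle.
#'
#' @param kset a [kmer_set()].
#' @param warn_above warn when `n` exceeds this size (default `1e5`).
#' @return character vector of weak canonical k-mers (sorted by code), with
#'   attribute `n_tests` giving the number of pair tests executed.
#' @export
weak_pairwise <- function(kset, warn_above = 1e5) {
  stopifnot(inherits(kset, "kmer_set"))
  n <- n_kmers(kset)
  if (n > warn_above)
    warning(sprintf("full pairwise comparison on n = %d is quadratic", n))
  res <- full_pairwise_cpp(kset$codes, kset$k)
  out <- raw_decode_cpp(res$weak, kset$k, drop_markbit = FALSE)
  attr(out, "n_tests") <- res$n_tests
  out
}

#' Weak k-mers by neighborhood generation
#'
#' For each canonical k-mer, generates the canonical codes of its `3k`
#' Hamming-distance-1 neighbours and looks them up in the set; every hit
#' marks both the k-mer and the discovered neighbour. A substituted k-mer
#' can canonicalize back onto its origin; such self-hits are ignored.
#'
#' In oracle mode (default) every member is processed fully. With
#' `early_exit = TRUE` (the baseline-benchmark behaviour), members already
#' marked are skipped and the neighbour scan stops at the first hit; the
#' returned weak set is identical.
#'
#' @param kset a [kmer_set()].
#' @param early_exit skip already-marked members and stop at the first
#'   neighbour found (default `FALSE`).
#' @return character vector of weak canonical k-mers (sorted by code).
#' @export
weak_neighborhood <- function(kset, early_exit = FALSE) {
  stopifnot(inherits(kset, "kmer_set"))
  res <- neighborhood_cpp(kset$codes, kset$k, isTRUE(early_exit))
  raw_decode_cpp(res, kset$k, drop_markbit = FALSE)
}
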