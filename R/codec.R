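# Integer codec for k-mers.
#
# A k-mer over ACGT is encoded as a base-4 integer with A=0, C=1, G=2, T=3,
# first character most significant: enc(TACG) = (3012)_4 = 198. Numeric codes
# cross the R boundary as doubles and are therefore exact only for k <= 26
# (2k <= 52 mantissa bits); every function here also has a character-vector
# interface that is exact for all k <= 31, and the array pipeline keeps codes
# in packed 64-bit form throughout.

KMAX_NUMERIC <- 26L

check_k_numeric <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k != as.integer(k))
    abort("`k` must be a single integer")
  k <- as.integer(k)
  if (k < 2L || k > 31L)
    abort(sprintf("`k` must be between 2 and 31, got %d", k))
  if (k > KMAX_NUMERIC)
    abort(sprintf(
      "numeric k-mer codes are exact only for k <= %d; use the character interface or the array pipeline for k = %d",
      KMAX_NUMERIC, k))
  k
}

#' Encode k-mers as base-4 integers
#'
#' Maps each DNA k-mer to its integer code using the lexicographic digit
#' assignment A=0, C=1, G=2, T=3 with the first character as the most
#' significant digit, e.g. `kmer_encode("TACG")` is `(3012)_4 = 198`.
#'
#' Codes are returned as doubles and are exact for k up to 26. For longer
#' k-mers work with the character interface of the other codec functions or
#' with [kmer_set()] / [expand_kmers()], which keep codes in packed 64-bit
#' form.
#'
#' @param seq character vector of k-mers (ACGT only, all the same length,
#'   2 <= k <= 26 for the numeric return value).
#' @return numeric vector of integer codes in `[0, 4^k)`.
#' @examples
#' kmer_encode(c("TACG", "CGTA", "AAAA"))
#' @export
kmer_encode <- function(seq) {
  if (!is.character(seq) || length(seq) == 0L) abort("`seq` must be a non-empty character vector")
  k <- unique(nchar(seq))
  if (length(k) != 1L) abort("all k-mers must have the same length")
  encode_cpp(seq, check_k_numeric(k))
}

#' Decode integer codes back to k-mer strings
#'
#' Inverse of [kmer_encode()]: `kmer_decode(kmer_encode(s), nchar(s))`
#' returns `s`.
#'
#' @param code numeric vector of codes in `[0, 4^k)`.
#' @param k k-mer length (2 to 26 for numeric codes).
#' @return character vector of k-mers.
#' @examples
#' kmer_decode(c(198, 108), k = 4)
#' @export
kmer_decode <- function(code, k) {
  decode_cpp(as.numeric(code), check_k_numeric(k))
}

#' Reverse complement on k-mers or their codes
#'
#' Computed entirely on the integer representation (bitwise complement over
#' 2k bits followed by 2-bit group reversal); no string round trip.
#'
#' @param x character vector of k-mers, or numeric codes (then `k` is
#'   required).
#' @param k k-mer length; only used (and required) for numeric `x`.
#' @return same type as `x`.
#' @examples
#' kmer_revcomp("TACG")
#' kmer_revcomp(198, k = 4)   # 108, the code of CGTA
#' @export
kmer_revcomp <- function(x, k = NULL) {
  if (is.character(x)) return(rc_str_cpp(x))
  if (is.null(k)) abort("`k` is required for numeric codes")
  rc_code_cpp(as.numeric(x), check_k_numeric(k))
}

#' Canonical code of a k-mer
#'
#' The canonical code is `max(enc(x), enc(rc(x)))`, so a k-mer and its
#' reverse complement (the same double-stranded molecule) share one code:
#' `cc(TACG) = cc(CGTA) = max(198, 108) = 198`.
#'
#' @inheritParams kmer_revcomp
#' @return same type as `x`: canonical k-mer strings or canonical codes.
#' @examples
#' kmer_canonical(c("TACG", "CGTA"))
#' kmer_canonical(108, k = 4)
#' @export
kmer_canonical <- function(x, k = NULL) {
  if (is.character(x)) return(canonical_str_cpp(x))
  if (is.null(k)) abort("`k` is required for numeric codes")
  canonical_code_cpp(as.numeric(x), check_k_numeric(k))
}

check_pair <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) abort("inputs must be non-empty")
  n <- max(length(x), length(y))
  if (n %% length(x) != 0L || n %% length(y) != 0L)
    abort("input lengths must recycle evenly")
  invisible(n)
}

#' Bit-parallel Hamming distance between k-mers
#'
#' Number of differing positions, computed on the 2k-bit codes: the XOR of
#' the two patterns is folded onto the even bit of each 2-bit group and the
#' population count of the folded mask is the distance.
#'
#' @param x,y character k-mers or numeric codes (recycled to a common
#'   length).
#' @param k k-mer length; required for numeric input.
#' @return integer vector of Hamming distances.
#' @examples
#' kmer_hamming("AAAA", "ATTT")   # 3
#' @export
kmer_hamming <- function(x, y, k = NULL) {
  check_pair(x, y)
  if (is.character(x) && is.character(y)) return(hamming_str_cpp(x, y))
  if (is.null(k)) abort("`k` is required for numeric codes")
  hamming_cpp(as.numeric(x), as.numeric(y), check_k_numeric(k))
}

#' Test whether the Hamming distance is at most 1
#'
#' Decided without a population count: the folded difference mask `h` has at
#' most one set bit iff `h & (h - 1) == 0`.
#'
#' @inheritParams kmer_hamming
#' @return logical vector.
#' @examples
#' kmer_hamming_leq1("AAAA", "AAAT")   # TRUE
#' @export
kmer_hamming_leq1 <- function(x, y, k = NULL) {
  check_pair(x, y)
  if (is.character(x) && is.character(y)) return(hd_at_most_1_str_cpp(x, y))
  if (is.null(k)) abort("`k` is required for numeric codes")
  hd_at_most_1_cpp(as.numeric(x), as.numeric(y), check_k_numeric(k))
}

#' Canonical Hamming distance between double-stranded k-mers
#'
#' `H(x, y) = min(d(x, y), d(x, rc(y)))`: the distance between the
#' molecules, not the literal strings. For example
#' `kmer_canonical_hamming("AAAA", "ATTT")` is 1, because ATTT is
#' equivalent to its reverse complement AAAT.
#'
#' @inheritParams kmer_hamming
#' @return integer vector of canonical Hamming distances.
#' @examples
#' kmer_canonical_hamming("AAAA", "ATTT")   # 1
#' @export
kmer_canonical_hamming <- function(x, y, k = NULL) {
  check_pair(x, y)
  if (is.character(x) && is.character(y)) return(canonical_hamming_str_cpp(x, y))
  if (is.null(k)) abort("`k` is required for numeric codes")
  canonical_hamming_cpp(as.numeric(x), as.numeric(y), check_k_numeric(k))
}
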