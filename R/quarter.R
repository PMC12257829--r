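# Quarter: pairwise tests in small buckets. With the array closed under
# reverse complement, at least one orientation of every weak pair has its
# single difference in the third quarter s1 or the last quarter s2 of the
# k-mer. Phase 1 buckets by the (ell + |s1|)-prefix (difference in s2);
# phase 2 swaps the s1/s2 sections within each ell-prefix block, locally
# re-sorts and buckets by the swapped (ell + |s2|)-prefix (difference in
# s1).

#' Quarter section lengths of a k-mer
#'
#' Splits k into the prefix `ell = floor(k/2)`, the third quarter `s1` and
#' the last quarter `s2`, with the third quarter the longer one when the
#' remainder is odd (for odd k this puts the middle position into `s1`).
#' For example k = 25 splits as 12 + 7 + 6.
#'
#' @param k k-mer length, 4 to 31.
#' @return named list with integer elements `ell`, `len_s1`, `len_s2`.
#' @examples
#' partition_lengths(25)   # ell 12, s1 7, s2 6
#' @export
partition_lengths <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 4L || k > 31L)
    abort("`k` must be between 4 and 31 (smaller k has empty quarters)")
  ell <- k %/% 2L
  r <- k - ell
  list(ell = ell, len_s1 = (r + 1L) %/% 2L, len_s2 = r %/% 2L)
}

#' Swap the third- and last-quarter sections of k-mers
#'
#' The first `ell` characters are unchanged; the former `s2` block moves to
#' positions `ell+1 .. ell+len_s2` and the former `s1` block follows. For
#' unequal section lengths the blocks have unequal widths, so the operation
#' is length-preserving only in total. It is an involution when
#' `len_s1 == len_s2`.
#'
#' @param x character k-mers, or numeric codes (then `k` is required;
#'   numeric codes are exact for k <= 26).
#' @param k k-mer length; required for numeric `x`.
#' @param spec section lengths, default [partition_lengths()] of k.
#' @return same type as `x`.
#' @examples
#' swap_sections("ACGTA")   # spec (2, 2, 1): "ACAGT"
#' @export
swap_sections <- function(x, k = NULL, spec = NULL) {
  if (is.character(x)) {
    k <- unique(nchar(x))
    if (length(k) != 1L) abort("all k-mers must have the same length")
    if (is.null(spec)) spec <- partition_lengths(k)
    p <- substr(x, 1L, spec$ell)
    s1 <- substr(x, spec$ell + 1L, spec$ell + spec$len_s1)
    s2 <- substr(x, spec$ell + spec$len_s1 + 1L, k)
    return(paste0(p, s2, s1))
  }
  if (is.null(k)) abort("`k` is required for numeric codes")
  k <- check_k_numeric(k)
  if (is.null(spec)) spec <- partition_lengths(k)
  if (spec$ell + spec$len_s1 + spec$len_s2 != k)
    abort("section lengths must sum to k")
  swap_sections_cpp(as.numeric(x), k, spec$len_s1, spec$len_s2)
}

#' One bucketed pairwise marking pass
#'
#' Partitions the array into maximal runs sharing their first `prefix_len`
#' characters (one linear scan, no hashing) and tests every unordered pair
#' within each run with the bit-parallel distance-at-most-1 test; both
#' members of a passing pair are marked. Runs of length 1 need no work.
#'
#' @param arr a `kmer_array`.
#' @param prefix_len shared-prefix length defining the buckets.
#' @return a `kmer_array` with mark bits set.
#' @export
bucket_pairwise_pass <- function(arr, prefix_len) {
  stopifnot(inherits(arr, "kmer_array"))
  new_kmer_array(arr$k,
                 bucket_pairwise_pass_cpp(arr$stored, arr$k,
                                          as.integer(prefix_len)),
                 chunk = attr(arr, "chunk"), s = attr(arr, "s"))
}

#' Mark weak k-mers with the Quarter algorithm
#'
#' Phase 1 runs [bucket_pairwise_pass()] with prefix `ell + len_s1`
#' (catching single differences in the last quarter). Phase 2 works within
#' each maximal `ell`-prefix block on a scratch copy with the s1/s2 sections
#' swapped, locally re-sorted and bucketed by the swapped `ell + len_s2`
#' prefix (catching differences in the third quarter); marks map back to the
#' original entries positionally. Differences in the first half are covered
#' by the reverse-complement pair; use [propagate_orientation()] (or
#' [mark_weak()]) afterwards.
#'
#' @param arr a `kmer_array` with `k >= 4`.
#' @param g chunk prefix length (`4^g` independent chunks, default 0).
#' @param chunk_order optional permutation of `1:4^g` (result is
#'   order-invariant).
#' @return a `kmer_array` with mark bits set.
#' @export
quarter_mark <- function(arr, g = 0, chunk_order = NULL) {
  stopifnot(inherits(arr, "kmer_array"))
  if (arr$k < 4L) abort("quarter_mark requires k >= 4")
  ranges <- resolve_ranges(arr, g, chunk_order)
  new_kmer_array(arr$k,
                 mark_ranges_cpp(arr$stored, arr$k, "quarter", 1L, ranges,
                                 FALSE),
                 chunk = attr(arr, "chunk"), s = attr(arr, "s"))
}
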