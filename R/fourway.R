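# FourWay: recursive 4-way merge-style comparison over the sorted expanded
# array. A pair at canonical Hamming distance 1 appears twice in the array
# (as {x, y} and {rc(x), rc(y)}), once with the difference in the first half
# and once in the second half, so it suffices to process the second half:
# partition into maximal blocks sharing the floor(k/2)-prefix and recurse
# from depth floor(k/2) + 1. Orientation propagation afterwards unifies the
# two orientations ([propagate_orientation()]).

resolve_ranges <- function(arr, g, chunk_order) {
  bounds <- prefix_chunk_bounds(arr, g)
  m <- cbind(bounds$start, bounds$end)
  if (!is.null(chunk_order)) {
    chunk_order <- as.integer(chunk_order)
    if (!setequal(chunk_order, seq_len(nrow(m))))
      abort("`chunk_order` must be a permutation of 1..4^g")
    m <- m[chunk_order, , drop = FALSE]
  }
  m
}

#' Mark weak k-mers with the FourWay algorithm
#'
#' Runs the recursive 4-way comparison on every maximal block of entries
#' sharing their length-`floor(k/2)` prefix, starting at depth
#' `floor(k/2) + 1`. Intervals of length at most `tau` are finished with
#' direct bit-parallel pairwise tests (the FourWay+Pairwise hybrid);
#' `tau = 1` disables the hybrid. The threshold and the chunking only affect
#' speed, never the result.
#'
#' Marks identify one orientation of each weak pair; use
#' [propagate_orientation()] (or the [mark_weak()] driver) to obtain the
#' weak canonical set.
#'
#' @param arr a `kmer_array` (see [expand_kmers()]).
#' @param tau interval length threshold for switching to pairwise testing
#'   (default 30; robust anywhere in roughly 20..70).
#' @param g chunk prefix length: the array is processed as `4^g` independent
#'   prefix chunks (default 0, one chunk).
#' @param full_depth if `TRUE`, recurse over the whole array from depth 1
#'   instead of second-half blocks (testing variant; catches first-half
#'   differences directly, requires `g = 0`).
#' @param chunk_order optional permutation of `1:4^g` giving the chunk
#'   execution order (the result is order-invariant).
#' @return a `kmer_array` with mark bits set.
#' @export
fourway_mark <- function(arr, tau = 30, g = 0, full_depth = FALSE,
                         chunk_order = NULL) {
  stopifnot(inherits(arr, "kmer_array"))
  tau <- as.integer(tau)
  if (is.na(tau) || tau < 1L) abort("`tau` must be >= 1")
  if (full_depth && g != 0)
    abort("`full_depth = TRUE` requires g = 0 (chunk prefixes would hide first-half differences)")
  ranges <- resolve_ranges(arr, g, chunk_order)
  new_kmer_array(arr$k,
                 mark_ranges_cpp(arr$stored, arr$k, "fourway", tau, ranges,
                                 isTRUE(full_depth)),
                 chunk = attr(arr, "chunk"), s = attr(arr, "s"))
}

#' Run the 4-way recursion on a single interval
#'
#' Low-level entry point: processes `[start, end)` at the given depth
#' (contract: all k-mers in the interval share their first `depth - 1`
#' characters). Every k-mer whose sole difference to another k-mer of the
#' interval lies at a position `>= depth` is marked. Intervals of length at
#' most `tau` are handled pairwise.
#'
#' @inheritParams subinterval_starts
#' @param tau pairwise switch threshold (`1` disables the hybrid).
#' @return a `kmer_array` with mark bits set.
#' @export
fourway_interval <- function(arr, start, end, depth, tau = 1) {
  stopifnot(inherits(arr, "kmer_array"))
  new_kmer_array(arr$k,
                 fourway_interval_cpp(arr$stored, arr$k, as.integer(start),
                                      as.integer(end), as.integer(depth),
                                      as.integer(tau)),
                 chunk = attr(arr, "chunk"), s = attr(arr, "s"))
}
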