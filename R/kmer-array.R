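# ExpandedArray: the sorted, orientation-closed array of stored values
# (code << 1 | markbit) that both marking algorithms operate on. Sorting the
# stored values orders by code because the mark sits in the least significant
# bit; every suffix/prefix extraction masks bit 0.

new_kmer_array <- function(k, stored, chunk = NA_integer_, s = 0L) {
  structure(list(k = as.integer(k), stored = stored),
            chunk = chunk, s = as.integer(s), class = "kmer_array")
}

#' Expand a canonical set into the sorted orientation-closed array
#'
#' For each canonical code `c` the output contains both `c` and `rc(c)`
#' (once if they coincide, i.e. for self-reverse-complementary k-mers),
#' shifted left one bit with the weak-mark bit clear, sorted ascending.
#'
#' @param kset a [kmer_set()].
#' @return a `kmer_array` of length `2 * n_kmers(kset)` minus the number of
#'   self-reverse-complementary canonical codes.
#' @examples
#' expand_kmers(kmer_set("TACG"))   # entries CGTA, TACG
#' @export
expand_kmers <- function(kset) {
  stopifnot(inherits(kset, "kmer_set"))
  new_kmer_array(kset$k, expand_cpp(kset$codes, kset$k))
}

#' Chunked low-memory expansion
#'
#' Splits the input set into `4^s` chunks by the length-`s` prefix of the
#' *expanded* entries (both orientations): chunk `j` holds exactly the
#' forward and reverse-complement codes whose first `s` characters encode
#' the integer `j`. The union of the chunks equals [expand_kmers()] of the
#' whole set; each chunk is individually sorted. `s = 0` yields a single
#' chunk identical to the unchunked expansion.
#'
#' @param kset a [kmer_set()].
#' @param s prefix length, 0 to `floor(k/2)`.
#' @return list of `4^s` `kmer_array` objects (possibly empty), chunk `j`
#'   (0-based prefix value) at list position `j + 1`.
#' @export
chunked_expand <- function(kset, s) {
  stopifnot(inherits(kset, "kmer_set"))
  s <- as.integer(s)
  if (is.na(s) || s < 0L || s > kset$k %/% 2L)
    abort("`s` must be in [0, floor(k/2)]")
  lapply(seq_len(4L^s) - 1L, function(j) {
    new_kmer_array(kset$k, extract_chunk_cpp(kset$codes, kset$k, s, j),
                   chunk = j, s = s)
  })
}

#' Weak-mark bits of an expanded array
#'
#' @param arr a `kmer_array`.
#' @return logical vector, `TRUE` where the entry carries the weak mark.
#' @export
kmer_marks <- function(arr) {
  stopifnot(inherits(arr, "kmer_array"))
  raw_markbits_cpp(arr$stored)
}

#' Entry k-mers of an expanded array
#'
#' @param arr a `kmer_array`.
#' @return character vector of the entries (both orientations), in array
#'   order.
#' @export
array_kmers <- function(arr) {
  stopifnot(inherits(arr, "kmer_array"))
  raw_decode_cpp(arr$stored, arr$k, drop_markbit = TRUE)
}

#' Validate the expanded-array invariants
#'
#' Checks strict sortedness (ignoring mark bits), distinctness, and
#' orientation closure (the reverse complement of every entry is present).
#'
#' @param arr a `kmer_array`.
#' @return invisibly `arr`; aborts with an informative message on violation.
#' @export
validate_kmer_array <- function(arr) {
  stopifnot(inherits(arr, "kmer_array"))
  chk <- check_array_cpp(arr$stored, arr$k)
  if (!chk$sorted) abort("expanded array is not sorted")
  if (!chk$distinct) abort("expanded array contains duplicate k-mers")
  if (!chk$closed) abort("expanded array is not closed under reverse complement")
  invisible(arr)
}

#' Character-class start pointers within an interval
#'
#' For an interval `[start, end)` (0-based, half-open) whose k-mers share
#' their first `depth - 1` characters, returns the start pointer of each
#' character class at position `depth` plus the end sentinel, found by one
#' linear scan. The shared-prefix precondition is a documented contract and
#' is not checked.
#'
#' @param arr a `kmer_array`.
#' @param start,end 0-based half-open interval bounds.
#' @param depth 1-based position under comparison.
#' @return named integer vector `c(a, c, g, t, end)` of 0-based pointers.
#' @export
subinterval_starts <- function(arr, start, end, depth) {
  stopifnot(inherits(arr, "kmer_array"))
  q <- subinterval_starts_cpp(arr$stored, arr$k, as.integer(start),
                              as.integer(end), as.integer(depth))
  stats::setNames(q, c("a", "c", "g", "t", "end"))
}

#' Prefix-defined chunk bounds
#'
#' Partitions the array into the `4^g` intervals of entries sharing each
#' length-`g` prefix. Empty chunks are allowed; concatenating the chunks
#' reproduces the whole array.
#'
#' @param arr a `kmer_array`.
#' @param g prefix length, 0 to `floor(k/2)`.
#' @return tibble with columns `prefix` (0-based integer value of the
#'   length-`g` prefix), `start`, `end` (0-based half-open bounds) and `n`.
#' @export
prefix_chunk_bounds <- function(arr, g) {
  stopifnot(inherits(arr, "kmer_array"))
  g <- as.integer(g)
  if (is.na(g) || g < 0L || g > arr$k %/% 2L)
    abort("`g` must be in [0, floor(k/2)]")
  m <- prefix_chunk_bounds_cpp(arr$stored, arr$k, g)
  tibble(prefix = seq_len(nrow(m)) - 1L, start = m[, 1L], end = m[, 2L],
         n = m[, 2L] - m[, 1L])
}

#' @export
length.kmer_array <- function(x) length(x$stored) %/% 8L

#' @export
print.kmer_array <- function(x, ...) {
  cat(sprintf("<kmer_array> k = %d, %d entries, %d marked weak\n",
              x$k, n_kmers(x), sum(kmer_marks(x))))
  invisible(x)
}

#' @rdname expand_kmers
#' @param x a `kmer_array`.
#' @param ... unused.
#' @export
as_tibble.kmer_array <- function(x, ...) {
  tibble(kmer = array_kmers(x), marked = kmer_marks(x))
}

# canonical kmer_set view of an array (counts unknown: all 1)
array_to_kset <- function(arr) {
  codes <- array_canonical_cpp(arr$stored, arr$k)
  new_kmer_set(arr$k, codes, rep(1L, length(codes) %/% 8L))
}
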