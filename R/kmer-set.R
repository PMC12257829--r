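# CanonicalKmerSet: distinct canonical codes with occurrence counts
# saturated at 2 (distinguishing "once" from "more than once" is all the
# uniqueness classification needs). Codes live in a raw vector packing
# little-endian uint64 values, exact for all k <= 31.

new_kmer_set <- function(k, codes, counts) {
  structure(list(k = as.integer(k), codes = codes, counts = counts),
            class = "kmer_set")
}

#' Build a canonical k-mer set from k-mer strings
#'
#' Canonicalizes, deduplicates and counts the given k-mers. Counts saturate
#' at 2; duplicated input k-mers (in either orientation) accumulate.
#'
#' @param kmers character vector of k-mers (ACGT, equal lengths, k in 2..31).
#' @param counts optional integer occurrence counts per input k-mer
#'   (default 1 each); counts of canonical duplicates are summed, then
#'   saturated at 2.
#' @return a `kmer_set`: list with elements `k`, `codes` (packed 64-bit
#'   canonical codes, sorted), `counts` (integer, 1 or 2).
#' @examples
#' kmer_set(c("TACG", "CGTA", "AAAA"))
#' @export
kmer_set <- function(kmers, counts = NULL) {
  if (!is.character(kmers)) abort("`kmers` must be a character vector")
  if (length(kmers) == 0L) return(new_kmer_set(2L, raw(0), integer(0)))
  k <- unique(nchar(kmers))
  if (length(k) != 1L) abort("all k-mers must have the same length")
  if (k < 2L || k > 31L) abort("k must be between 2 and 31")
  if (is.null(counts)) counts <- rep(1L, length(kmers))
  if (length(counts) != length(kmers)) abort("`counts` must match `kmers`")
  res <- make_kset_cpp(str_to_raw_codes_cpp(kmers, as.integer(k)),
                       as.integer(counts), as.integer(k))
  new_kmer_set(k, res$codes, res$counts)
}

#' Count canonical k-mers in FASTA sequences
#'
#' Every length-k window consisting solely of A, C, G, T contributes the
#' canonical code of the window; windows overlapping any other character are
#' skipped. Counts saturate at 2. Canonicalization already folds the two
#' strands, so the reverse strand is not scanned separately.
#'
#' @param fasta path to a FASTA file (read with
#'   [Biostrings::readDNAStringSet()]), or a character vector of sequences.
#' @param k k-mer length, 2 to 31.
#' @return a [kmer_set()].
#' @examples
#' count_kmers(c("TACGT", "AANAA"), k = 4)
#' @export
count_kmers <- function(fasta, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > 31L) abort("k must be between 2 and 31")
  seqs <- fasta_sequences(fasta)
  res <- count_kmers_cpp(seqs, k)
  new_kmer_set(k, res$codes, res$counts)
}

fasta_sequences <- function(fasta) {
  if (inherits(fasta, "DNAStringSet")) return(as.character(fasta))
  if (!is.character(fasta)) abort("`fasta` must be a file path or sequences")
  if (length(fasta) == 1L && file.exists(fasta)) {
    ss <- Biostrings::readDNAStringSet(fasta)
    if (length(ss) == 0L) abort(sprintf("no sequences in '%s'", fasta))
    out <- as.character(ss)
    names(out) <- names(ss)
    return(out)
  }
  fasta
}

#' @export
length.kmer_set <- function(x) length(x$codes) %/% 8L

#' Number of canonical k-mers in a set or entries in an array
#'
#' @param x a `kmer_set` or `kmer_array`.
#' @return integer count.
#' @export
n_kmers <- function(x) {
  stopifnot(inherits(x, "kmer_set") || inherits(x, "kmer_array"))
  if (inherits(x, "kmer_set")) length(x$codes) %/% 8L else length(x$stored) %/% 8L
}

#' Canonical k-mer strings of a set
#'
#' @param x a `kmer_set`.
#' @return character vector of canonical k-mers, in sorted code order.
#' @export
set_kmers <- function(x) {
  stopifnot(inherits(x, "kmer_set"))
  raw_decode_cpp(x$codes, x$k, drop_markbit = FALSE)
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("<kmer_set> k = %d, %d distinct canonical k-mers (%d with count >= 2)\n",
              x$k, n_kmers(x), sum(x$counts >= 2L)))
  invisible(x)
}

#' @rdname kmer_set
#' @param x a `kmer_set`.
#' @param ... unused.
#' @export
as_tibble.kmer_set <- function(x, ...) {
  tibble(kmer = set_kmers(x), count = x$counts)
}
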