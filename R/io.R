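# On-disk formats.
#
# Array file: flat little-endian 64-bit unsigned integers (the stored values
# code << 1 | markbit, sorted), written as-is; a JSON sidecar header at
# <path>.hdr records magic string, k, the s-chunk id (NA when unchunked) and
# the entry count. Results additionally round-trip through a tab-separated
# text table (canonical k-mer, weak/strong label) plus a JSON summary.

ARRAY_MAGIC <- "strongmark-array-v1"

#' Write / read a k-mer array in the flat binary format
#'
#' The payload file holds the stored values as little-endian uint64; the
#' sidecar `<path>.hdr` is a JSON header with the magic string, `k`, the
#' chunk id and the entry count.
#'
#' @param arr a `kmer_array`.
#' @param path payload file path (header goes to `<path>.hdr`).
#' @return `write_kmer_array` returns `path` invisibly; `read_kmer_array`
#'   returns the `kmer_array`.
#' @export
write_kmer_array <- function(arr, path) {
  stopifnot(inherits(arr, "kmer_array"))
  writeBin(arr$stored, path)
  header <- list(magic = ARRAY_MAGIC, k = arr$k,
                 chunk = attr(arr, "chunk"), s = attr(arr, "s"),
                 n = n_kmers(arr))
  jsonlite::write_json(header, paste0(path, ".hdr"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_kmer_array
#' @export
read_kmer_array <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) abort(sprintf("missing header file '%s'", hdr_path))
  header <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  if (!identical(header$magic, ARRAY_MAGIC))
    abort(sprintf("'%s' is not a strongmark array (bad magic)", path))
  stored <- readBin(path, what = "raw", n = file.size(path))
  if (length(stored) != 8L * header$n)
    abort("array payload length does not match header entry count")
  new_kmer_array(header$k, stored,
                 chunk = if (is.null(header$chunk)) NA_integer_ else header$chunk,
                 s = if (is.null(header$s)) 0L else header$s)
}

#' Write / read a weak-marking result
#'
#' Writes three files: `<prefix>.tsv` (one canonical k-mer and its
#' weak/strong label per line, tab-separated), `<prefix>.json` (machine-
#' readable summary: k, n, weak and strong counts, parameters) and
#' `<prefix>.bin` (+ `.hdr`), the canonical codes with mark bits in the flat
#' binary array format. The round trip restores k and the weak/strong sets.
#'
#' @param res a `weak_result`.
#' @param prefix output path prefix.
#' @return `write_results` returns the three file paths invisibly;
#'   `read_results` returns a `weak_result` (counts are not persisted and
#'   read back as 1).
#' @export
write_results <- function(res, prefix) {
  stopifnot(inherits(res, "weak_result"))
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  bin <- paste0(prefix, ".bin")
  df <- data.frame(kmer = c(weak_kmers(res), strong_kmers(res)),
                   label = rep(c("weak", "strong"),
                               c(length(res$weak) %/% 8L,
                                 length(res$strong) %/% 8L)))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  g <- glance(res)
  jsonlite::write_json(c(as.list(g), res$params), js, auto_unbox = TRUE)
  # canonical codes with the mark bit in stored-value convention
  marked <- raw_union_cpp(raw_shift_mark_cpp(res$weak, TRUE),
                          raw_shift_mark_cpp(res$strong, FALSE))
  write_kmer_array(new_kmer_array(res$k, marked), bin)
  invisible(c(tsv = tsv, json = js, bin = bin))
}

#' @rdname write_results
#' @export
read_results <- function(prefix) {
  arr <- read_kmer_array(paste0(prefix, ".bin"))
  js <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  marks <- kmer_marks(arr)
  codes <- raw_unshift_cpp(arr$stored)
  weak <- raw_subset_cpp(codes, which(marks))
  strong <- raw_subset_cpp(codes, which(!marks))
  new_weak_result(arr$k, weak, strong,
                  rep(1L, length(weak) %/% 8L), rep(1L, length(strong) %/% 8L),
                  if (is.null(js$algorithm)) "unknown" else js$algorithm,
                  list(tau = js$tau, g = js$g, threads = js$threads, s = js$s))
}
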