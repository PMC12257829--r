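# Orchestration: expansion (optionally s-chunked), chunk scheduling,
# algorithm dispatch, orientation propagation, and the weak/strong result
# container. Chunks own disjoint array slices during marking and propagation
# is a separate sequential pass, so the result is identical for every
# (algorithm, tau, g, s, thread count, chunk order) combination.

#' Propagate marks across orientations
#'
#' A marking pass only finds the orientation pair whose single difference
#' lies in the processed positions; an entry is weak iff it *or its reverse
#' complement* is marked. Collapses marks to the canonical representative.
#'
#' @param arr a marked `kmer_array`.
#' @return character vector of weak canonical k-mers (sorted by code).
#' @export
propagate_orientation <- function(arr) {
  stopifnot(inherits(arr, "kmer_array"))
  raw_decode_cpp(propagate_cpp(arr$stored, arr$k, check_closure = TRUE), arr$k, drop_markbit = FALSE)
}

new_weak_result <- function(k, weak, strong, counts_weak, counts_strong,
                            algorithm, params) {
  structure(list(k = as.integer(k), weak = weak, strong = strong,
                 counts_weak = counts_weak, counts_strong = counts_strong,
                 algorithm = algorithm, params = params),
            class = "weak_result")
}

#' Identify weak canonical k-mers
#'
#' High-level driver: expands the canonical set into the sorted
#' orientation-closed array (optionally in `4^s` prefix chunks to bound
#' memory), dispatches the selected algorithm over `4^g` prefix chunks,
#' propagates marks across orientations and returns the weak/strong
#' partition of the input set. The result is identical for every algorithm
#' and every parameter combination.
#'
#' @param x a [kmer_set()] or an already expanded `kmer_array`.
#' @param algorithm one of `"fourway_pairwise"` (default), `"fourway"`
#'   (pure recursion, `tau = 1`), `"quarter"`, `"pairwise"` or
#'   `"neighborhood"` (the naive baselines). Dashes may be used instead of
#'   underscores.
#' @param tau pairwise switch threshold for `fourway_pairwise`
#'   (default 30).
#' @param g chunk prefix length; default `min(5, floor(k/2))`.
#' @param threads requested worker count. Chunks are independent jobs over
#'   disjoint slices; this implementation executes them sequentially (in
#'   `chunk_order` if given), so `threads` only caps the effective
#'   parallelism reported by [schedule_chunks()].
#' @param s input-split prefix length for chunked expansion (default 0).
#' @param chunk_order optional permutation of `1:4^g` fixing the chunk
#'   execution order.
#' @return a `weak_result`; see [weak_kmers()], [strong_kmers()],
#'   [tidy.weak_result()], [glance.weak_result()].
#' @examples
#' ks <- kmer_set(c("AAAAA", "AAAAC", "GGTGG"))
#' mark_weak(ks, algorithm = "quarter", g = 0)
#' @export
mark_weak <- function(x, algorithm = c("fourway_pairwise", "fourway",
                                       "quarter", "pairwise", "neighborhood"),
                      tau = 30, g = NULL, threads = 1, s = 0,
                      chunk_order = NULL) {
  algorithm <- gsub("-", "_", algorithm, fixed = TRUE)
  algorithm <- match.arg(algorithm)
  if (inherits(x, "kmer_array")) {
    kset <- array_to_kset(x)
    arr0 <- x
  } else if (inherits(x, "kmer_set")) {
    kset <- x
    arr0 <- NULL
  } else {
    abort("`x` must be a kmer_set or kmer_array")
  }
  k <- kset$k
  if (is.null(g)) g <- min(5L, k %/% 2L)
  if (threads < 1) abort("`threads` must be >= 1")

  if (algorithm %in% c("pairwise", "neighborhood")) {
    weak_chr <- if (algorithm == "pairwise") weak_pairwise(kset)
                else weak_neighborhood(kset)
    weak_raw <- if (length(weak_chr)) str_to_raw_codes_cpp(weak_chr, k) else raw(0)
  } else {
    alg <- if (algorithm == "quarter") "quarter" else "fourway"
    tau_eff <- if (algorithm == "fourway") 1L else as.integer(tau)
    chunks <- if (!is.null(arr0) || s == 0) {
      list(if (is.null(arr0)) expand_kmers(kset) else arr0)
    } else {
      chunked_expand(kset, s)
    }
    weak_raw <- raw(0)
    for (chunk in chunks) {
      if (n_kmers(chunk) == 0L) next
      ranges <- resolve_ranges(chunk, g, chunk_order)
      marked <- mark_ranges_cpp(chunk$stored, k, alg, tau_eff, ranges, FALSE)
      weak_raw <- raw_union_cpp(weak_raw, propagate_cpp(marked, k, s == 0L))
    }
  }

  is_weak <- raw_in_cpp(kset$codes, weak_raw)
  strong_raw <- raw_setdiff_cpp(kset$codes, weak_raw)
  new_weak_result(k, weak_raw, strong_raw,
                  kset$counts[is_weak], kset$counts[!is_weak],
                  algorithm,
                  list(tau = tau, g = g, threads = threads, s = s))
}

#' Weak / strong canonical k-mers of a result
#'
#' @param res a `weak_result` from [mark_weak()].
#' @return character vector of canonical k-mers, sorted by code.
#' @export
weak_kmers <- function(res) {
  stopifnot(inherits(res, "weak_result"))
  raw_decode_cpp(res$weak, res$k, drop_markbit = FALSE)
}

#' @rdname weak_kmers
#' @export
strong_kmers <- function(res) {
  stopifnot(inherits(res, "weak_result"))
  raw_decode_cpp(res$strong, res$k, drop_markbit = FALSE)
}

#' @export
print.weak_result <- function(x, ...) {
  nw <- length(x$weak) %/% 8L
  ns <- length(x$strong) %/% 8L
  cat(sprintf("<weak_result> k = %d, %d canonical k-mers: %d weak, %d strong (algorithm %s)\n",
              x$k, nw + ns, nw, ns, x$algorithm))
  invisible(x)
}

#' Tidy a weak-marking result
#'
#' @param x a `weak_result`.
#' @param ... unused.
#' @return tibble with one row per canonical k-mer of the input set:
#'   `kmer`, `count` (saturated at 2), `weak` (logical).
#' @export
tidy.weak_result <- function(x, ...) {
  dplyr::arrange(
    tibble(kmer = c(weak_kmers(x), strong_kmers(x)),
           count = c(x$counts_weak, x$counts_strong),
           weak = rep(c(TRUE, FALSE),
                      c(length(x$weak) %/% 8L, length(x$strong) %/% 8L))),
    .data$kmer)
}

#' One-row summary of a weak-marking result
#'
#' @param x a `weak_result`.
#' @param ... unused.
#' @return tibble with `k`, `n`, `n_weak`, `n_strong`, `weak_fraction` and
#'   `algorithm`.
#' @export
glance.weak_result <- function(x, ...) {
  nw <- length(x$weak) %/% 8L
  ns <- length(x$strong) %/% 8L
  tibble(k = x$k, n = nw + ns, n_weak = nw, n_strong = ns,
         weak_fraction = if (nw + ns > 0) nw / (nw + ns) else NA_real_,
         algorithm = x$algorithm)
}

#' Chunk execution plan
#'
#' Assigns the `4^g` prefix chunks of an array to workers round-robin over
#' the non-empty chunks. Chunks touch disjoint slices during marking, so any
#' interleaving yields the same marks; the effective parallelism is
#' `min(threads, number of non-empty chunks)`.
#'
#' @param arr a `kmer_array`.
#' @param g chunk prefix length.
#' @param threads requested worker count.
#' @return tibble with columns `chunk` (0-based prefix value), `start`,
#'   `end`, `n`, `worker`; attribute `effective_parallelism`.
#' @export
schedule_chunks <- function(arr, g, threads = 1) {
  stopifnot(inherits(arr, "kmer_array"))
  if (threads < 1) abort("`threads` must be >= 1")
  bounds <- prefix_chunk_bounds(arr, g)
  nonempty <- which(bounds$n > 0L)
  worker <- rep(NA_integer_, nrow(bounds))
  if (length(nonempty))
    worker[nonempty] <- ((seq_along(nonempty) - 1L) %% as.integer(threads)) + 1L
  out <- tibble(chunk = bounds$prefix, start = bounds$start, end = bounds$end,
                n = bounds$n, worker = worker)
  attr(out, "effective_parallelism") <-
    min(as.integer(threads), length(nonempty))
  out
}
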