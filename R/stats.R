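# Uniqueness classification and block-wise genomic profiles. A canonical
# k-mer with count >= 2 is non-unique; with count 1 it is weakly unique when
# weak (a single substitution can hit another member of the set) and
# strongly unique otherwise.

UNIQUENESS_LEVELS <- c("strongly_unique", "weakly_unique", "non_unique")

#' Classify canonical k-mers by uniqueness
#'
#' Combines occurrence counts with the weak marking: count >= 2 gives
#' `non_unique`; count 1 gives `weakly_unique` when the k-mer is weak and
#' `strongly_unique` otherwise.
#'
#' @param kset the [kmer_set()] the weak set was computed from.
#' @param weak a `weak_result` from [mark_weak()], or a character vector of
#'   weak canonical k-mers.
#' @return tibble with columns `kmer`, `count`, `class` (factor with levels
#'   strongly_unique, weakly_unique, non_unique), one row per canonical
#'   k-mer, sorted by code; carries the packed codes in attribute `codes`
#'   for downstream lookups.
#' @export
classify_kmers <- function(kset, weak) {
  stopifnot(inherits(kset, "kmer_set"))
  if (inherits(weak, "weak_result")) {
    if (weak$k != kset$k) abort("`weak` was computed for a different k")
    weak_raw <- weak$weak
  } else if (is.character(weak)) {
    weak_raw <- if (length(weak)) {
      w <- str_to_raw_codes_cpp(kmer_canonical(weak), kset$k)
      raw_subset_cpp(w, raw_order_cpp(w))
    } else raw(0)
  } else {
    abort("`weak` must be a weak_result or character vector")
  }
  labels <- classify_cpp(kset$codes, kset$counts, weak_raw, kset$k)
  out <- tibble(kmer = set_kmers(kset), count = kset$counts,
                class = factor(UNIQUENESS_LEVELS[labels],
                               levels = UNIQUENESS_LEVELS))
  attr(out, "codes") <- kset$codes
  attr(out, "k") <- kset$k
  out
}

#' Block-wise uniqueness profile of sequences
#'
#' Assigns every valid k-mer start position (0-based, leftmost base; windows
#' containing non-ACGT characters are excluded from numerator and
#' denominator) to the half-open block `[i*B, (i+1)*B)` containing it and
#' computes per-block class fractions over the valid starts. Blocks without
#' a valid start get `NA` fractions.
#'
#' @param fasta path to a FASTA file or character vector of sequences.
#' @param k k-mer length.
#' @param classes classification of every canonical k-mer occurring in the
#'   sequences, as returned by [classify_kmers()]; a missing k-mer is an
#'   inconsistency error.
#' @param block_size block size in base pairs (default 100000).
#' @return tibble of class `kmer_block_profile` with columns `seqname`,
#'   `block_start`, `block_end` (0-based half-open), `n_valid_starts`,
#'   `frac_strongly_unique`, `frac_weakly_unique`, `frac_non_unique`.
#' @export
block_profile <- function(fasta, k, classes, block_size = 1e5) {
  k <- as.integer(k)
  seqs <- fasta_sequences(fasta)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  codes <- attr(classes, "codes")
  if (is.null(codes)) {
    codes <- str_to_raw_codes_cpp(classes$kmer, k)
    ord <- raw_order_cpp(codes)
    codes <- raw_subset_cpp(codes, ord)
    labels <- as.integer(classes$class)[ord]
  } else {
    if (!identical(attr(classes, "k"), k))
      abort("`classes` was computed for a different k")
    labels <- as.integer(classes$class)
  }
  rows <- lapply(seq_along(seqs), function(i) {
    counts <- block_counts_cpp(seqs[i], k, codes, labels, block_size)
    nb <- nrow(counts)
    if (nb == 0L) return(NULL)
    len <- nchar(seqs[[i]])
    valid <- counts[, 1L]
    denom <- ifelse(valid > 0L, valid, NA_integer_)
    tibble(seqname = names(seqs)[i],
           block_start = (seq_len(nb) - 1) * block_size,
           block_end = pmin(seq_len(nb) * block_size, len),
           n_valid_starts = valid,
           frac_strongly_unique = counts[, 2L] / denom,
           frac_weakly_unique = counts[, 3L] / denom,
           frac_non_unique = counts[, 4L] / denom)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("kmer_block_profile", class(out))
  out
}

#' Plot a block-wise uniqueness profile
#'
#' Stacked per-block class fractions along each sequence, one facet per
#' sequence. Blocks without valid k-mer starts are dropped.
#'
#' @param object a `kmer_block_profile` from [block_profile()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.kmer_block_profile <- function(object, ...) {
  long <- tidyr_pivot(object)
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$block_start, y = .data$fraction,
                               fill = .data$class)) +
    ggplot2::geom_col(width = max(object$block_end - object$block_start),
                      position = "stack") +
    ggplot2::facet_wrap(~seqname, ncol = 1L) +
    ggplot2::scale_fill_manual(values = c(strongly_unique = "#1b9e77",
                                          weakly_unique = "#377eb8",
                                          non_unique = "#ff7f00")) +
    ggplot2::labs(x = "position (bp)", y = "fraction of k-mer starts",
                  fill = "class")
}

# long format without importing tidyr for a single reshape
tidyr_pivot <- function(profile) {
  keep <- !is.na(profile$frac_strongly_unique)
  p <- profile[keep, , drop = FALSE]
  dplyr::bind_rows(lapply(UNIQUENESS_LEVELS, function(cl) {
    tibble(seqname = p$seqname, block_start = p$block_start,
           class = factor(cl, levels = UNIQUENESS_LEVELS),
           fraction = p[[paste0("frac_", cl)]])
  }))
}
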