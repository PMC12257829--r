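# Generators for extremal (all-weak, all-strong) and random datasets. All
# randomness flows from a single seed through R's RNG, so outputs are
# byte-identical across runs.

#' Generate an all-weak expanded array
#'
#' Draws random k-mers amounting to roughly a quarter of the target size,
#' adds for each a Hamming-distance-1 neighbour (one position replaced by
#' its complement), closes under reverse complement, sorts, and assembles
#' complete pair groups until the array holds exactly `n` entries. Every
#' canonical k-mer in the result is weak. Entry groups have size 4 (3 when a
#' member is its own reverse complement), so targets not expressible as
#' `4a + 3b` over the realized groups are infeasible; any `n` divisible by 4
#' always works.
#'
#' @param n target number of entries in the expanded array (>= 2).
#' @param k k-mer length, 2 to 31.
#' @param seed RNG seed.
#' @return a `kmer_array` of exactly `n` entries, all canonical k-mers weak.
#' @export
gen_all_weak <- function(n, k, seed) {
  k <- as.integer(k)
  arr <- withr::with_seed(seed, gen_all_weak_cpp(n, k))
  new_kmer_array(k, arr)
}

#' Generate an all-strong expanded array
#'
#' Draws an oversized random orientation-closed set, marks its weak k-mers
#' (FourWay+Pairwise plus orientation propagation), removes them, and keeps
#' strong canonical codes until the array holds exactly `n` entries.
#' Removing elements cannot create weakness, so every canonical k-mer in the
#' result is strong. If too few strong k-mers survive, the draw is retried
#' with a larger oversampling factor before giving up.
#'
#' @param n target number of entries in the expanded array.
#' @param k k-mer length, 4 to 31.
#' @param seed RNG seed.
#' @param oversample initial oversampling factor for the candidate draw.
#' @return a `kmer_array` of exactly `n` entries, all canonical k-mers
#'   strong.
#' @export
gen_all_strong <- function(n, k, seed, oversample = 1.3) {
  k <- as.integer(k)
  n <- as.numeric(n)
  if (k < 4L || k > 31L) abort("`k` must be between 4 and 31")
  capacity <- (4^k + if (k %% 2 == 0) 2^k else 0) / 2
  withr::with_seed(seed, {
    for (fac in oversample * c(1, 1.5, 2.5, 4)) {
      m <- min(ceiling(n / 2 * fac) + 8, capacity)
      codes <- draw_canonical_cpp(m, k)
      stored <- expand_cpp(codes, k)
      marked <- mark_ranges_cpp(stored, k, "fourway", 30L,
                                matrix(c(0L, length(stored) %/% 8L), 1L), FALSE)
      weak <- propagate_cpp(marked, k, TRUE)
      strong <- raw_setdiff_cpp(codes, weak)
      out <- assemble_strong_cpp(strong, k, n)
      if (length(out) > 0L) return(new_kmer_array(k, out))
    }
    abort(sprintf(
      "retry exhausted: could not assemble %g strong entries for k = %d (space too dense)",
      n, k))
  })
}

#' Generate a random canonical k-mer set
#'
#' Draws `n` distinct canonical codes uniformly (rejection sampling over the
#' canonical space) and assigns each a count of 2 with probability
#' `p_count2`, else 1.
#'
#' @param n number of distinct canonical k-mers.
#' @param k k-mer length, 2 to 31.
#' @param seed RNG seed.
#' @param p_count2 probability of a count of 2 (default 0).
#' @return a [kmer_set()].
#' @export
gen_random <- function(n, k, seed, p_count2 = 0) {
  k <- as.integer(k)
  res <- withr::with_seed(seed, gen_random_cpp(n, k, p_count2))
  new_kmer_set(k, res$codes, res$counts)
}

#' Number of distinct canonical k-mers for a given k
#'
#' `(4^k + p) / 2` where `p` is the number of self-reverse-complementary
#' k-mers (`2^k` for even k, none for odd k). Useful to cap feasible set
#' sizes.
#'
#' @param k k-mer length.
#' @return numeric count.
#' @export
canonical_capacity <- function(k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 31L) abort("`k` must be in 1..31")
  (4^k + if (k %% 2 == 0) 2^k else 0) / 2
}

#' Synthetic dataset dispatcher
#'
#' Convenience wrapper over [gen_all_weak()], [gen_all_strong()] and
#' [gen_random()] keyed by mode, as used by the command-line interface.
#'
#' @param mode `"all_weak"`, `"all_strong"` or `"random"` (dashes allowed).
#' @param n target size (expanded entries for the extremal modes, distinct
#'   canonical k-mers for `"random"`).
#' @param k k-mer length.
#' @param seed RNG seed.
#' @param ... passed through to the underlying generator.
#' @return a `kmer_array` (extremal modes) or [kmer_set()] (`"random"`).
#' @export
synth_kmers <- function(mode, n, k, seed, ...) {
  mode <- gsub("-", "_", mode, fixed = TRUE)
  switch(match.arg(mode, c("all_weak", "all_strong", "random")),
         all_weak = gen_all_weak(n, k, seed, ...),
         all_strong = gen_all_strong(n, k, seed, ...),
         random = gen_random(n, k, seed, ...))
}
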