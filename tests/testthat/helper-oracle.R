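# Independent pure-R string oracles: no shared code with the compiled paths.

r_revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

r_hamming <- function(x, y) {
  mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, x, y, USE.NAMES = FALSE)
}

r_canonical_hamming <- function(x, y) {
  pmin(r_hamming(x, y), r_hamming(x, r_revcomp(y)))
}

r_canonical <- function(s) {
  rc <- r_revcomp(s)
  ifelse(s >= rc, s, rc)  # lexicographic max equals code max (A<C<G<T)
}

# naive weak set over canonical k-mer strings (tiny n only)
r_weak_set <- function(kmers) {
  kmers <- unique(r_canonical(kmers))
  n <- length(kmers)
  weak <- logical(n)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (r_canonical_hamming(kmers[i], kmers[j]) == 1) {
          weak[i] <- TRUE
          weak[j] <- TRUE
        }
      }
    }
  }
  sort(kmers[weak])
}

random_kmers <- function(n, k) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, character(1))
}

expect_weak_equal <- function(res, expected_chr) {
  expect_setequal(weak_kmers(res), expected_chr)
}
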