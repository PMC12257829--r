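test_that("encoding follows the base-4 digit convention", {
  expect_identical(kmer_encode("TACG"), 198)   # (3012)_4
  expect_identical(kmer_encode("AAAA"), 0)
  expect_identical(kmer_encode("ACGT"), 27)    # 0*64 + 1*16 + 2*4 + 3
  expect_identical(kmer_encode("CGTA"), 108)
  expect_error(kmer_encode("ACGN"), "non-ACGT")
  expect_error(kmer_encode("A"), "between 2 and 31")
})

test_that("decode inverts encode", {
  expect_identical(kmer_decode(198, 4), "TACG")
  expect_identical(kmer_decode(0, 4), "AAAA")
  expect_identical(kmer_decode(108, 4), "CGTA")
  expect_error(kmer_decode(256, 4), "out of range")
  withr::with_seed(11, {
    for (k in c(2L, 7L, 15L, 26L)) {
      s <- random_kmers(25, k)
      expect_identical(kmer_decode(kmer_encode(s), k), s)
    }
  })
})

test_that("reverse complement works on the integer code", {
  expect_identical(kmer_revcomp(198, k = 4), 108)
  expect_identical(kmer_revcomp(0, k = 4), 255)   # AAAA -> TTTT
  expect_identical(kmer_revcomp("TACG"), "CGTA")
  withr::with_seed(12, {
    for (k in c(2L, 9L, 20L, 31L)) {
      s <- random_kmers(25, k)
      expect_identical(kmer_revcomp(s), r_revcomp(s))
      expect_identical(kmer_revcomp(kmer_revcomp(s)), s)  # involution
    }
  })
})

test_that("canonical code is max of the two orientations, idempotent and orientation-invariant", {
  expect_identical(kmer_canonical(198, k = 4), 198)
  expect_identical(kmer_canonical(108, k = 4), 198)
  expect_identical(kmer_canonical(27, k = 4), 27)   # ACGT is its own rc
  withr::with_seed(13, {
    for (k in c(4L, 11L, 31L)) {
      s <- random_kmers(40, k)
      cc <- kmer_canonical(s)
      expect_identical(kmer_canonical(cc), cc)
      expect_identical(kmer_canonical(kmer_revcomp(s)), cc)
      expect_identical(cc, r_canonical(s))
    }
  })
})

test_that("bit-parallel hamming distance matches the character-wise oracle", {
  expect_identical(kmer_hamming("AAAA", "ATTT"), 3L)
  expect_identical(kmer_hamming("AAAA", "AAAT"), 1L)
  expect_identical(kmer_hamming("TACG", "TACG"), 0L)
  expect_error(kmer_hamming("AAAA", "AAAAA"), "different length")
  withr::with_seed(14, {
    for (k in 2:31) {
      x <- random_kmers(40, k)
      y <- random_kmers(40, k)
      expect_identical(kmer_hamming(x, y), as.integer(r_hamming(x, y)))
    }
  })
})

test_that("the popcount-free distance-at-most-1 test agrees with the distance", {
  expect_true(kmer_hamming_leq1("AAAA", "AAAT"))
  expect_true(kmer_hamming_leq1("TACG", "TACG"))
  expect_false(kmer_hamming_leq1("AAAA", "ATTT"))
  withr::with_seed(15, {
    for (k in 2:31) {
      x <- random_kmers(40, k)
      y <- random_kmers(40, k)
      # mix in guaranteed-close pairs so distance <= 1 occurs for large k
      pos <- sample(k, 20, replace = TRUE)
      z <- vapply(seq_len(20), function(i) {
        s <- strsplit(x[i], "")[[1]]
        s[pos[i]] <- sample(c("A", "C", "G", "T"), 1)
        paste(s, collapse = "")
      }, character(1))
      expect_identical(kmer_hamming_leq1(x, y), r_hamming(x, y) <= 1)
      expect_identical(kmer_hamming_leq1(x[1:20], z), r_hamming(x[1:20], z) <= 1)
    }
  })
})

test_that("canonical hamming distance is the min over orientations and symmetric", {
  expect_identical(kmer_canonical_hamming("AAAA", "ATTT"), 1L)
  expect_identical(kmer_canonical_hamming("TACG", "TACG"), 0L)
  withr::with_seed(16, {
    for (k in c(3L, 8L, 21L, 31L)) {
      x <- random_kmers(30, k)
      y <- random_kmers(30, k)
      h <- kmer_canonical_hamming(x, y)
      expect_identical(h, as.integer(r_canonical_hamming(x, y)))
      expect_identical(h, kmer_canonical_hamming(y, x))
      expect_identical(h, kmer_canonical_hamming(kmer_revcomp(x), y))
      expect_identical(h, kmer_canonical_hamming(kmer_revcomp(x), kmer_revcomp(y)))
    }
  })
})

test_that("symmetry of canonical distance holds exhaustively for all 4-mer pairs", {
  all4 <- kmer_decode(0:255, 4)
  idx <- expand.grid(i = 1:64, j = 1:64)  # a dense corner of the space
  x <- all4[idx$i]
  y <- all4[idx$j]
  expect_identical(kmer_canonical_hamming(x, y), kmer_canonical_hamming(y, x))
})

test_that("numeric codes refuse k beyond the double-exact range", {
  expect_error(kmer_decode(1, 27), "exact only")
  expect_silent(kmer_decode(1, 26))
})
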