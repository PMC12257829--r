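test_that("quarter section lengths follow the floor/ceil split", {
  expect_equal(partition_lengths(25), list(ell = 12L, len_s1 = 7L, len_s2 = 6L))
  expect_equal(partition_lengths(24), list(ell = 12L, len_s1 = 6L, len_s2 = 6L))
  expect_equal(partition_lengths(13), list(ell = 6L, len_s1 = 4L, len_s2 = 3L))
  for (k in 4:31) {
    p <- partition_lengths(k)
    expect_equal(p$ell + p$len_s1 + p$len_s2, k)
    expect_true((p$len_s1 - p$len_s2) %in% c(0L, 1L))
    # the middle position of odd k falls inside s1
    if (k %% 2 == 1) {
      mid <- (k + 1L) %/% 2L
      expect_true(mid > p$ell && mid <= p$ell + p$len_s1)
    }
  }
  expect_error(partition_lengths(3), "between 4 and 31")
})

test_that("section swap exchanges s1 and s2 blocks", {
  expect_identical(swap_sections("ACGT"), "ACTG")    # spec (2, 1, 1)
  expect_identical(swap_sections("ACGTA"), "ACAGT")  # spec (2, 2, 1)
  # numeric route agrees with the string route
  expect_identical(swap_sections(kmer_encode("ACGTA"), k = 5),
                   kmer_encode("ACAGT"))
  withr::with_seed(41, {
    for (k in c(8L, 12L, 24L)) {  # equal section widths: involution
      s <- random_kmers(20, k)
      expect_identical(swap_sections(swap_sections(s)), s)
    }
    for (k in c(6L, 13L)) {       # unequal widths: total length kept
      s <- random_kmers(20, k)
      sw <- swap_sections(s)
      expect_identical(nchar(sw), nchar(s))
      expect_identical(substr(sw, 1, k %/% 2), substr(s, 1, k %/% 2))
    }
  })
})

test_that("bucketed pairwise pass marks exactly the in-bucket distance-1 pairs", {
  # hand-built triple in one bucket: H(x,y) = 1, others >= 2
  x <- "AAAACGGA"
  y <- "AAAACGGC"
  z <- "AAAACGTT"
  arr <- expand_kmers(kmer_set(c(x, y, z)))
  out <- bucket_pairwise_pass(arr, prefix_len = 4)
  marked <- array_kmers(out)[kmer_marks(out)]
  expect_setequal(kmer_canonical(marked), r_weak_set(c(x, y)))

  # all-distinct prefixes: no comparisons, no marks
  arr2 <- expand_kmers(kmer_set(c("AACCGGTT", "CCAATTGG")))
  expect_false(any(kmer_marks(bucket_pairwise_pass(arr2, prefix_len = 8))))
})

test_that("phase coverage: last-quarter, third-quarter and first-half differences", {
  for (k in c(12L, 13L, 25L)) {
    p <- partition_lengths(k)
    base <- substr(strrep("ACGTTGCAAC", 4), 1, k)
    for (pos in c(k,                       # in s2 (phase 1)
                  p$ell + 1L,              # in s1 (phase 2)
                  1L,                      # first half, via rc pair
                  if (k %% 2 == 1) (k + 1L) %/% 2L)) {  # odd-k middle
      y <- base
      substr(y, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                     substr(base, pos, pos))[1]
      ks <- kmer_set(c(base, y))
      weak <- propagate_orientation(quarter_mark(expand_kmers(ks)))
      expect_setequal(weak, r_weak_set(c(base, y)))
    }
  }
})

test_that("quarter agrees with the oracles and with fourway on random sets", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      k <- sample(4:31, 1)
      n <- min(sample(1:800, 1), canonical_capacity(k))
      ks <- gen_random(n, k, seed = 2000 + rep)
      expected <- as.character(weak_pairwise(ks))
      expect_weak_equal(mark_weak(ks, "quarter", g = sample(0:2, 1)), expected)
      expect_identical(weak_kmers(mark_weak(ks, "quarter")),
                       weak_kmers(mark_weak(ks, "fourway_pairwise")))
    }
  })
})

test_that("quarter leaves the array order and membership intact", {
  ks <- gen_random(500, 9, seed = 43)
  arr <- expand_kmers(ks)
  out <- quarter_mark(arr)
  # same entries in the same order; only mark bits may differ
  expect_identical(array_kmers(out), array_kmers(arr))
  expect_silent(validate_kmer_array(out))
})

test_that("extremal datasets under quarter", {
  aw <- gen_all_weak(2000, 13, seed = 44)
  expect_equal(glance(mark_weak(aw, "quarter"))$weak_fraction, 1.0)
  as <- gen_all_strong(2000, 13, seed = 44)
  expect_equal(glance(mark_weak(as, "quarter"))$weak_fraction, 0.0)
})
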