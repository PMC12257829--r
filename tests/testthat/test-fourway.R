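mark_and_propagate <- function(arr, ...) {
  propagate_orientation(fourway_mark(arr, ...))
}

test_that("trivial intervals produce no marks", {
  arr <- expand_kmers(kmer_set("ACGTA"))
  out <- fourway_interval(arr, 0, 1, 1, tau = 1)
  expect_false(any(kmer_marks(out)))
  empty <- expand_kmers(kmer_set(character(0)))
  expect_equal(n_kmers(fourway_mark(empty)), 0L)
})

test_that("a last-position pair is found and matches the pairwise oracle", {
  ks <- kmer_set(c("AAAAA", "AAAAC", "GGTGG"))
  arr <- fourway_mark(expand_kmers(ks), tau = 1)
  weak <- propagate_orientation(arr)
  expect_setequal(weak, r_weak_set(c("AAAAA", "AAAAC")))
})

test_that("the pairwise switch threshold never changes the output", {
  withr::with_seed(31, {
    ks <- gen_random(200, 11, seed = 310)
    arr <- expand_kmers(ks)
    ref <- propagate_orientation(fourway_mark(arr, tau = 1))
    for (tau in c(2, 24, 30, 100)) {
      expect_identical(mark_and_propagate(arr, tau = tau), ref)
    }
  })
})

test_that("chunking and chunk order never change the output", {
  ks <- gen_random(2000, 13, seed = 32)
  arr <- expand_kmers(ks)
  ref <- mark_and_propagate(arr, tau = 30, g = 0)
  for (g in 1:3) {
    withr::with_seed(33 + g, ord <- sample(4^g))
    expect_identical(mark_and_propagate(arr, tau = 30, g = g,
                                        chunk_order = ord), ref)
  }
})

test_that("second-half processing plus propagation equals full-depth recursion", {
  # pairs differing at position 1 (first half) are only caught through the
  # reverse-complement pair; the full-depth variant catches them directly
  for (k in c(8L, 9L)) {
    base <- strrep("ACGT", 8)
    x <- substr(base, 1, k)
    for (pos in c(1L, (k + 1L) %/% 2L)) {  # first position and middle
      y <- x
      substr(y, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                     substr(x, pos, pos))[1]
      ks <- kmer_set(c(x, y, strrep("G", k)))
      arr <- expand_kmers(ks)
      weak_second <- mark_and_propagate(arr, tau = 1)
      weak_full <- propagate_orientation(
        fourway_mark(arr, tau = 1, full_depth = TRUE))
      expect_setequal(weak_second, r_weak_set(c(x, y)))
      expect_identical(sort(weak_full), sort(weak_second))
    }
  }
})

test_that("fourway agrees with the naive oracles on random sets", {
  withr::with_seed(34, {
    for (rep in 1:25) {
      k <- sample(5:31, 1)
      n <- min(sample(1:800, 1), canonical_capacity(k))
      ks <- gen_random(n, k, seed = 1000 + rep)
      expected <- weak_pairwise(ks)
      expect_weak_equal(mark_weak(ks, "fourway", g = sample(0:2, 1)),
                        as.character(expected))
      expect_weak_equal(mark_weak(ks, "fourway_pairwise",
                                  tau = sample(c(2, 24, 30, 100), 1)),
                        as.character(expected))
    }
  })
})

test_that("extremal datasets are fully weak or fully strong", {
  aw <- gen_all_weak(2000, 21, seed = 35)
  expect_equal(glance(mark_weak(aw, "fourway_pairwise"))$weak_fraction, 1.0)
  as <- gen_all_strong(2000, 21, seed = 35)
  expect_equal(glance(mark_weak(as, "fourway_pairwise"))$weak_fraction, 0.0)
})

test_that("runtime grows subquadratically in n", {
  gen <- function(n) expand_kmers(gen_random(n, 25, seed = 36))
  a1 <- gen(50000)
  a2 <- gen(100000)
  t1 <- system.time(fourway_mark(a1, tau = 30))[["elapsed"]]
  t2 <- system.time(fourway_mark(a2, tau = 30))[["elapsed"]]
  expect_lt(t2, max(3 * t1, t1 + 0.5))  # floor guards against timer noise
})
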