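test_that("all five algorithms return the same weak/strong partition", {
  ks <- gen_random(600, 9, seed = 61, p_count2 = 0.3)
  results <- lapply(c("fourway", "fourway_pairwise", "quarter", "pairwise",
                      "neighborhood"),
                    function(a) mark_weak(ks, a))
  ref <- results[[1]]
  for (r in results[-1]) {
    expect_identical(weak_kmers(r), weak_kmers(ref))
    expect_identical(strong_kmers(r), strong_kmers(ref))
  }
  # partition is exhaustive and disjoint
  td <- tidy(ref)
  expect_identical(sort(td$kmer), sort(set_kmers(ks)))
  expect_equal(sum(td$weak) + sum(!td$weak), n_kmers(ks))
})

test_that("the result is invariant under g, s, threads and chunk order", {
  ks <- gen_random(3000, 11, seed = 62)
  ref <- weak_kmers(mark_weak(ks, g = 0, s = 0, threads = 1))
  withr::with_seed(63, {
    for (g in 0:3) for (s in 0:2) for (threads in c(1, 4)) {
      ord <- sample(4^g)
      r <- mark_weak(ks, "fourway_pairwise", g = g, s = s, threads = threads,
                     chunk_order = ord)
      expect_identical(weak_kmers(r), ref)
    }
  })
})

test_that("empty and trivial inputs give empty partitions", {
  ks <- kmer_set(character(0))
  r <- mark_weak(ks)
  expect_length(weak_kmers(r), 0L)
  expect_length(strong_kmers(r), 0L)
})

test_that("orientation propagation unifies marks onto canonical codes", {
  # mark only the non-canonical orientation by hand and propagate
  ks <- kmer_set(c("AAAAA", "AAAAC"))
  arr <- fourway_mark(expand_kmers(ks), tau = 1)
  marks <- kmer_marks(arr)
  expect_true(any(marks))
  weak <- propagate_orientation(arr)
  expect_true(all(weak == kmer_canonical(weak)))
  expect_setequal(weak, kmer_canonical(c("AAAAA", "AAAAC")))

  # marks on both orientations still yield one canonical output
  arr2 <- fourway_mark(expand_kmers(ks), tau = 1, full_depth = TRUE)
  expect_identical(sort(propagate_orientation(arr2)), sort(weak))
})

test_that("propagation rejects an array that lost an orientation", {
  ks <- kmer_set(c("AAAAA", "AAAAC"))
  arr <- fourway_mark(expand_kmers(ks), tau = 1)
  # drop the last entry: rc of a marked entry goes missing
  broken <- arr
  broken$stored <- broken$stored[seq_len(length(broken$stored) - 8L)]
  expect_error(propagate_orientation(broken), "corrupted")
})

test_that("chunk scheduling covers all chunks and caps parallelism", {
  arr <- expand_kmers(gen_random(500, 9, seed = 64))
  plan0 <- schedule_chunks(arr, g = 0, threads = 16)
  expect_equal(nrow(plan0), 1L)
  expect_equal(attr(plan0, "effective_parallelism"), 1L)

  plan2 <- schedule_chunks(arr, g = 2, threads = 16)
  expect_equal(nrow(plan2), 16L)
  expect_equal(attr(plan2, "effective_parallelism"),
               min(16L, sum(plan2$n > 0)))
  expect_equal(sum(plan2$n), n_kmers(arr))
})

test_that("results survive the text and binary round trip", {
  ks <- gen_random(200, 13, seed = 65)
  res <- mark_weak(ks)
  prefix <- file.path(withr::local_tempdir(), "out")
  paths <- write_results(res, prefix)
  expect_true(all(file.exists(paths)))

  # text format: kmer TAB label
  lines <- readLines(paths[["tsv"]])
  expect_true(all(grepl("^[ACGT]+\t(weak|strong)$", lines)))

  back <- read_results(prefix)
  expect_identical(weak_kmers(back), weak_kmers(res))
  expect_identical(strong_kmers(back), strong_kmers(res))
  expect_equal(back$k, res$k)
})

test_that("array files round trip and bad magic is rejected", {
  arr <- expand_kmers(gen_random(100, 9, seed = 66))
  path <- file.path(withr::local_tempdir(), "arr.bin")
  write_kmer_array(arr, path)
  back <- read_kmer_array(path)
  expect_identical(back$stored, arr$stored)
  expect_equal(back$k, arr$k)

  jsonlite::write_json(list(magic = "something-else", k = 9, n = 0),
                       paste0(path, ".hdr"), auto_unbox = TRUE)
  expect_error(read_kmer_array(path), "magic")
})

test_that("tidy and glance summarize the partition consistently", {
  ks <- gen_random(100, 9, seed = 67, p_count2 = 0.5)
  res <- mark_weak(ks)
  g <- glance(res)
  td <- tidy(res)
  expect_equal(g$n, nrow(td))
  expect_equal(g$n_weak, sum(td$weak))
  expect_equal(g$weak_fraction, g$n_weak / g$n)
  expect_true(all(td$count %in% 1:2))
})
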