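test_that("counting scans valid windows only and saturates at 2", {
  ks <- count_kmers("TACG", 4)
  expect_equal(n_kmers(ks), 1L)
  expect_identical(set_kmers(ks), "TACG")   # cc(TACG) = 198
  expect_identical(ks$counts, 1L)

  # AANAA, k = 2: windows AA, AA only (AN/NA skipped); cc(AA) = TT
  ks2 <- count_kmers("AANAA", 2)
  expect_identical(set_kmers(ks2), "TT")
  expect_identical(ks2$counts, 2L)

  # record shorter than k
  expect_equal(n_kmers(count_kmers("ACG", 4)), 0L)

  # count saturation: poly-A has many occurrences but count caps at 2
  ks3 <- count_kmers(strrep("A", 30), 5)
  expect_identical(ks3$counts, 2L)
})

test_that("counting reads multi-record FASTA files", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1", "TAC", "GT", ">r2", "AANAA"), fa)
  ks <- count_kmers(fa, 2)
  df <- as_tibble(ks)
  # r1 contributes TA, AC, CG, GT; r2 contributes AA twice
  expect_setequal(df$kmer, kmer_canonical(c("TA", "AC", "CG", "GT", "AA")))
  expect_identical(df$count[df$kmer == "TT"], 2L)
})

test_that("expansion is sorted, distinct and orientation-closed", {
  arr <- expand_kmers(kmer_set("TACG"))
  expect_identical(array_kmers(arr), c("CGTA", "TACG"))   # codes 108 < 198

  # palindrome collapses to one entry
  arr2 <- expand_kmers(kmer_set("ACGT"))
  expect_identical(array_kmers(arr2), "ACGT")

  withr::with_seed(21, {
    ks <- gen_random(100, 9, seed = 100)
    arr3 <- expand_kmers(ks)
    expect_silent(validate_kmer_array(arr3))
    pal <- sum(set_kmers(ks) == kmer_revcomp(set_kmers(ks)))
    expect_equal(n_kmers(arr3), 2L * n_kmers(ks) - pal)
  })
})

test_that("subinterval start pointers match a search-based oracle", {
  arr <- expand_kmers(kmer_set(c("AA", "AC", "GA", "GT")))
  # expanded entries sorted; compute pointers at depth 1 over whole array
  q <- subinterval_starts(arr, 0, n_kmers(arr), 1)
  first <- substr(array_kmers(arr), 1, 1)
  expect_equal(unname(q), c(
    0L,
    sum(first < "C"), sum(first < "G"), sum(first < "T"),
    n_kmers(arr)))

  # worked pair: entries CGTA, TACG at depth 1
  arr2 <- expand_kmers(kmer_set("TACG"))
  expect_equal(unname(subinterval_starts(arr2, 0, 2, 1)),
               c(0L, 0L, 1L, 1L, 2L))

  # empty interval: all pointers collapse to start
  expect_equal(unname(subinterval_starts(arr2, 1, 1, 2)),
               c(1L, 1L, 1L, 1L, 1L))

  # randomized agreement with binary search on decoded strings
  withr::with_seed(22, {
    ks <- gen_random(300, 7, seed = 300)
    arr3 <- expand_kmers(ks)
    km <- array_kmers(arr3)
    for (d in c(1L, 2L, 4L)) {
      # restrict to an interval sharing the first d-1 characters
      pre <- substr(km, 1, d - 1)
      runs <- rle(pre)
      ends <- cumsum(runs$lengths)
      starts <- c(0L, head(ends, -1))
      i <- which.max(runs$lengths)
      q <- subinterval_starts(arr3, starts[i], ends[i], d)
      chr <- substr(km[(starts[i] + 1):ends[i]], d, d)
      expect_equal(unname(q), c(
        starts[i],
        starts[i] + sum(chr < "C"), starts[i] + sum(chr < "G"),
        starts[i] + sum(chr < "T"), ends[i]))
    }
  })
})

test_that("prefix chunks partition the array", {
  ks <- kmer_set("TACG")
  arr <- expand_kmers(ks)   # entries CGTA, TACG
  b <- prefix_chunk_bounds(arr, 1)
  expect_equal(b$start, c(0L, 0L, 1L, 1L))
  expect_equal(b$end, c(0L, 1L, 1L, 2L))

  b0 <- prefix_chunk_bounds(arr, 0)
  expect_equal(nrow(b0), 1L)
  expect_equal(b0$end - b0$start, n_kmers(arr))

  withr::with_seed(23, {
    arr2 <- expand_kmers(gen_random(400, 9, seed = 400))
    for (g in 0:3) {
      b <- prefix_chunk_bounds(arr2, g)
      expect_equal(nrow(b), 4L^g)
      expect_equal(b$start, c(0L, head(b$end, -1)))   # contiguous partition
      expect_equal(b$end[4L^g], n_kmers(arr2))
    }
  })
  expect_error(prefix_chunk_bounds(arr, 3), "floor")
})

test_that("chunked expansion unions to the unchunked array", {
  ks <- kmer_set("TACG")
  chunks <- chunked_expand(ks, 1)
  expect_length(chunks, 4L)
  expect_identical(array_kmers(chunks[[2]]), "CGTA")   # prefix C (j = 1)
  expect_identical(array_kmers(chunks[[4]]), "TACG")   # prefix T (j = 3)
  expect_equal(n_kmers(chunks[[1]]), 0L)
  expect_equal(n_kmers(chunks[[3]]), 0L)

  ks2 <- gen_random(500, 9, seed = 24)
  whole <- array_kmers(expand_kmers(ks2))
  for (s in c(0L, 2L)) {
    parts <- unlist(lapply(chunked_expand(ks2, s), array_kmers))
    expect_identical(sort(parts), sort(whole))
  }
  expect_error(chunked_expand(ks2, 5), "floor")
})
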