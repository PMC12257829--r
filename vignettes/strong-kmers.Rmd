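---
title: "Identifying weak and strongly unique canonical k-mers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying weak and strongly unique canonical k-mers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strongmark)
```

## The problem

Alignment-free methods place sequenced DNA fragments by their k-mer content.
A k-mer that occurs at a single position in the indexed collection (a
*unique* k-mer) identifies that position unambiguously — but not robustly: a
single substitution (sequencing error, SNV) can turn it into a different
k-mer that happens to exist elsewhere in the collection, silently giving
wrong placement information. A unique k-mer whose entire Hamming-distance-1
neighbourhood is absent from the collection is *strongly unique*: no single
substitution can produce misleading evidence.

Because DNA is double stranded, a k-mer `x` and its reverse complement
`rc(x)` are the same molecule. Sets of k-mers are therefore stored as
*canonical* codes, and distance is the *canonical Hamming distance*

$$H(x, y) = \min\{\, d(x, y),\ d(x, \mathrm{rc}(y)) \,\},$$

where `d` is the ordinary (string) Hamming distance. Given a set `K` of
distinct canonical k-mers with occurrence counts, the computational core is:
mark every `x` in `K` for which another `y` in `K` with `H(x, y) = 1` exists
(a *weak* k-mer). Strongly unique k-mers are then exactly the count-1 k-mers
that are not weak; count-1 weak k-mers are *weakly unique*; count ≥ 2 k-mers
are *non-unique*. Counts saturate at 2 because nothing beyond
"once / more than once" is needed.

## Integer encoding and bit-parallel tests

A k-mer is a base-4 integer with digits A=0, C=1, G=2, T=3, first character
most significant: `enc(TACG) = (3012)_4 = 198`. The canonical code is the
maximum of the two orientations, so `cc(TACG) = cc(CGTA) = max(198, 108) =
198`. On the 2k-bit patterns `p`, `q`, the Hamming distance is computed
without loops: fold `u = p XOR q` onto the even bit of each 2-bit group,
`h = (u | (u >> 1)) & 0101...01`; the popcount of `h` is the distance, and
`h & (h - 1) == 0` decides "distance at most 1" without a popcount.

```{r codec}
kmer_encode(c("TACG", "CGTA"))
kmer_canonical("CGTA")
kmer_hamming("AAAA", "ATTT")            # strings differ in 3 positions
kmer_canonical_hamming("AAAA", "ATTT")  # but rc(ATTT) = AAAT is 1 away
```

Codes are limited to `k ≤ 31` so that the 2k bits plus one weak-mark bit fit
a 64-bit word. Inside the package, code arrays are kept in packed 64-bit
form (a raw vector), exact for every `k ≤ 31`. Numeric codes crossing into
R are doubles and therefore exact only up to `k = 26` (52 mantissa bits);
the codec functions enforce this and offer character interfaces for all
`k ≤ 31`. This split is deliberate: it keeps the user-facing API ordinary R
vectors while never rounding inside the algorithms.

## The expanded array

Both marking algorithms work on one substrate (`expand_kmers()`): the
sorted array of *both orientations* of every canonical k-mer, each entry
stored as `code << 1 | markbit`. Because the mark occupies the least
significant bit, sorting stored values orders by code, and marking during a
pass never perturbs later comparisons. A self-reverse-complementary k-mer
(possible only for even k) is stored once — the array holds distinct
k-mers. Closing the array under reverse complement is what turns ordinary
Hamming distance inside the algorithms into canonical Hamming distance for
the original set: every weak pair `{x, y}` appears twice, once as
`{x, y}` and once as `{rc(x), rc(y)}`, with the single difference in the
second half of the k-mer in one of the two appearances.

## FourWay and FourWay+Pairwise

`fourway_mark()` partitions the array into maximal blocks sharing their
length-`⌊k/2⌋` prefix (one linear scan) and runs a 4-way merge-style
recursion inside each block, starting at 1-based depth `⌊k/2⌋ + 1`. At
depth `d`, four cursors — one per character class at position `d` — walk
the interval in parallel; whenever two or more cursors hold the same
minimal `(k-d)`-suffix, the k-mers under them differ only at position `d`
and are marked. The minimal set is tracked as a 4-bit vector `v` (A=1, C=2,
G=4, T=8); `v & (v-1) != 0` detects a group of size ≥ 2. Recursion then
descends into the four sub-intervals at depth `d + 1`.

Starting at depth `⌊k/2⌋ + 1` covers every difference position: a
difference at position `i` is seen directly when `i ≥ ⌊k/2⌋ + 1` and
through the reverse-complement pair (difference at `k + 1 - i`) when
`i ≤ ⌈k/2⌉`; together that is all of `1..k`, for both parities of k. A
`full_depth` variant that recurses from depth 1 is kept for testing this
coverage argument; it must produce identical results after propagation, and
the test suite checks that it does.

The recursion is implemented iteratively with an explicit stack, so deep
k-mers cannot exhaust R's or C's call stack. Once an interval is shorter
than the threshold `tau`, all pairs are tested directly with the
bit-parallel distance test (*FourWay+Pairwise*); book-keeping for tiny
intervals costs more than the quadratic test. The default `tau = 30` sits
in the broad flat optimum (roughly 20–70); `tau = 1` disables the hybrid.
The threshold affects running time only — the mark set is identical for
every `tau`, which the tests assert.

## Quarter

`quarter_mark()` splits each k-mer as prefix `ℓ = ⌊k/2⌋`, third quarter
`s1 = ⌈(k-ℓ)/2⌉` and last quarter `s2 = ⌊(k-ℓ)/2⌋` (for k = 25:
12 + 7 + 6; the longer third quarter contains the middle position of odd
k). Because the array is closed under reverse complement, some orientation
of every weak pair differs inside `s1` or `s2`:

* Phase 1 buckets the array by the `(ℓ + |s1|)`-prefix and tests all pairs
  within a bucket — this catches differences in `s2`.
* Phase 2 works within each maximal `ℓ`-prefix block: swap the `s1` and
  `s2` sections of every entry, locally re-sort, bucket by the swapped
  `(ℓ + |s2|)`-prefix, and test all pairs — this catches differences in
  `s1`. The implementation uses a scratch copy of each block carrying
  (swapped code, original index), so marks map back positionally and the
  original array order is untouched; this is contract-equivalent to
  swapping in place and swapping back, and easier to verify.

A Hamming distance is invariant under any fixed permutation of positions,
so testing swapped codes is exact. Bucket runs are found by comparing
adjacent masked prefixes in one scan — no hashing. Quarter's cost is
quadratic within buckets, so it prefers large k (smaller buckets); for
small k the same loops are used without special-casing.

## One subtlety: near-palindromes

The expanded array contains both `x` and `rc(x)`. When
`d(x, rc(x)) = 1` — possible when the two wings of `x` are mutually
reverse-complementary and only the orientation of one position differs —
the pair `{x, rc(x)}` passes the distance test but represents a *single*
canonical k-mer, and weakness requires *another* member of the set. All
marking passes therefore refuse to mark a pair whose members are mutual
reverse complements. The naive neighbourhood oracle has the mirror rule: a
generated neighbour that canonicalizes back onto its origin is not a hit.
Without this rule the fast algorithms would over-mark relative to the
definition (the randomized oracle-equivalence suite catches it
immediately).

## Orientation propagation and the driver

A marking pass finds the orientation whose difference lies in the processed
positions, so `mark_weak()` finishes with a propagation pass: an entry is
weak iff it or its reverse complement is marked, collapsed onto the
canonical representative. Propagation on a full array validates that the rc
of every marked entry is present (a corrupted array otherwise).

Chunking happens at two levels, both by first-characters prefix and both
pure contracts on disjoint slices:

* `g` (default `min(5, ⌊k/2⌋)`) splits the *sorted array* into `4^g`
  chunks for parallel dispatch. Chunk boundaries are prefix boundaries with
  `g ≤ ⌊k/2⌋`, so no comparison block is ever split.
* `s` splits the *input set* before expansion (`chunked_expand()`), for
  machines that cannot hold the full expanded array; chunks are processed
  sequentially and their weak sets unioned. An `s`-chunk is not
  orientation-closed (the rc of an entry usually lives in another chunk),
  which is safe because every weak pair is caught in the chunk where its
  second-half-difference orientation lives; propagation skips the closure
  check for these chunks.

Execution here is sequential; `threads` caps the effective parallelism
reported by `schedule_chunks()` and documents the contract (chunks own
disjoint slices, so any interleaving gives identical marks). The test suite
asserts bit-identical results over the full cross-product of algorithm,
`tau`, `g`, `s`, thread count and randomized chunk order.

## Baselines as oracles

The two naive algorithms define the weak set independently:
`weak_pairwise()` tests all `n(n-1)/2` pairs; `weak_neighborhood()`
generates the `3k` canonical neighbour codes of every member and looks them
up. They agree with each other by construction of the problem, and every
fast path must agree with both, exactly, on randomized suites spanning
`k ∈ {5..31}` and `n` up to 2000 — plus an independent pure-R string-based
oracle on tiny sets, so the check does not rest on the compiled code alone.
The neighbourhood baseline's early-exit mode (skip already-marked members,
stop at the first hit) changes speed, not the result, and is off in oracle
mode.

## Synthetic data

The generators emulate the extremal regimes used to exercise the marking
algorithms, at desk scale (up to ~10^7 entries rather than billions):

* `gen_all_weak(n, k, seed)` draws random codes for a quarter of the
  target, creates for each a distance-1 partner by replacing one uniformly
  chosen nucleotide with its *complement* (so the partner is never the
  k-mer itself), closes under reverse complement and assembles disjoint
  pair groups until exactly `n` entries are reached. Groups have 4 entries
  (3 with a palindromic member), so `n` divisible by 4 is always feasible;
  other targets need rare palindromic groups and fail fast with an
  infeasibility error. Degenerate draws where the partner equals `rc` of
  the origin (a single canonical k-mer, hence *not* weak) are rejected and
  redrawn. Every canonical k-mer in the result is weak, a property the
  tests re-verify with the naive oracle rather than trusting the
  construction.
* `gen_all_strong(n, k, seed)` oversamples a random canonical set, marks
  and removes the weak k-mers, and keeps strong codes until exactly `n`
  entries remain. Removing members can only remove weakness, never create
  it, so the survivors stay strong; if too few survive, the draw retries
  with larger oversampling before giving up.
* `gen_random(n, k, seed)` draws distinct canonical codes uniformly by
  rejection; feasibility is checked against the exact canonical capacity
  `(4^k + [k even] 2^k) / 2`.

All randomness flows from R's RNG under a single seed, so outputs are
byte-identical across runs. What these datasets do *not* emulate: the
skewed k-mer composition, repeat structure and count spectrum of real
genomes. Passing on them demonstrates correctness of the marking logic and
the extremal weak fractions (exactly 1 and exactly 0), not performance or
classification behaviour on genomic data — the block-profile tests use
small constructed repeat/unique mosaics for that.

## Uniqueness classification and block profiles

`classify_kmers()` is a total three-way partition (count ≥ 2 →
non-unique; count 1 and weak → weakly unique; count 1 and strong →
strongly unique). `block_profile()` assigns each k-mer occurrence to the
half-open block `[iB, (i+1)B)` containing its 0-based *leftmost* base
(the start-position convention; block size default 100 000 bp), counting
k-mer positions rather than distinct k-mers, and computes per-block class
fractions over valid starts only. Windows containing non-ACGT characters
are excluded from both numerator and denominator; blocks with no valid
start report missing fractions. Occurrence positions are found by a second
scan of the sequences against the classification map, so no positions need
to be stored while counting.

## Numerical and design choices

* Canonical code = *maximum* of the two encodings (minimum is equally
  valid; the maximum convention is fixed here so printed example values
  reproduce).
* Non-ACGT characters break k-mer windows entirely; no IUPAC wildcard
  expansion.
* `k` is carried alongside every structure and never inferred from values.
* Interval bookkeeping is 0-based half-open throughout the array API,
  matching the slicing arithmetic of the algorithms; the documentation
  flags this at each entry point.
* The shared-prefix precondition of `subinterval_starts()` is a documented
  contract, not a runtime check — it sits on the hot path.
* Propagation finds reverse complements by binary search in the sorted
  array; no auxiliary hash index.
* Problem sizes in the test-suite: randomized equivalence over 500 sets
  with `n ≤ 2000`, extremal datasets of 10^4 entries, determinism on a
  10^5-k-mer set, and a timing comparison at 10^6 vs 2×10^6 25-mers —
  sizes at which the whole suite completes in well under a minute while
  still exercising every code path many times.

## Limitations

* `k ≤ 31` (64-bit stored values), `k ≥ 4` for Quarter.
* Hamming distance exactly 1 only; larger radii would need a different
  algorithmic approach.
* In-memory only; `s`-chunked construction bounds the expanded array, not
  the canonical input set.
* Counting is in-memory with saturation at 2; for genome-scale counting an
  external k-mer counter feeding `kmer_set()` is the intended route.
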