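# strongmark

Identify **weak** and **strongly unique** canonical k-mers in DNA sequence
collections.

A k-mer occurring at a single position of an indexed collection is *unique*
and makes a precise alignment-free anchor — but a single substitution can
turn it into a different k-mer that exists elsewhere, giving silently wrong
placement evidence. A unique k-mer with no Hamming-distance-1 neighbour
anywhere in the collection is **strongly unique**: robust against any single
substitution. Since DNA is double stranded, k-mers are handled as canonical
codes and distance is the canonical Hamming distance

    H(x, y) = min{ d(x, y), d(x, rc(y)) },

so the core task is: given a set *K* of distinct canonical k-mers, mark every
*x* ∈ *K* with another *y* ∈ *K* at H(x, y) = 1 (a **weak** k-mer).
Combined with occurrence counts (saturated at 2), this classifies every
k-mer as strongly unique (count 1, not weak), weakly unique (count 1, weak)
or non-unique (count ≥ 2).

The package implements three marking algorithms over a sorted,
orientation-closed array of 2k-bit integer codes (k ≤ 31, exact 64-bit
arithmetic in compiled code):

* **FourWay** — recursive 4-way merge-style comparison of character-class
  cursors; a group of entries sharing the minimal suffix at the current
  depth differs in exactly one position.
* **FourWay+Pairwise** (default) — the same recursion, switching to direct
  bit-parallel all-pairs testing on intervals shorter than a threshold
  (default 30).
* **Quarter** — bucket by shared ¾-prefix and test pairs inside buckets;
  a section swap plus local re-sort covers differences in the third
  quarter; reverse-complement closure covers the first half.

The two naive baselines (full pairwise comparison, 3k-neighbourhood
generation) are included and serve as ground-truth oracles; every algorithm
must reproduce their weak set exactly, which the test suite checks on
hundreds of randomized inputs. Synthetic generators produce extremal
datasets that are provably all-weak or all-strong, plus uniform random sets.

## Worked example

```r
library(strongmark)

fa <- system.file("extdata/synthetic_contigs.fa", package = "strongmark")
ks <- count_kmers(fa, k = 25)
ks
#> <kmer_set> k = 25, 722 distinct canonical k-mers (103 with count >= 2)

res <- mark_weak(ks, algorithm = "fourway_pairwise")
glance(res)
#> # A tibble: 1 × 6
#>       k     n n_weak n_strong weak_fraction algorithm
#>   <int> <int>  <int>    <int>         <dbl> <chr>
#> 1    25   722     12      710        0.0166 fourway_pairwise

cl <- classify_kmers(ks, res)
dplyr::count(cl, class)
#> # A tibble: 3 × 2
#>   class               n
#>   <fct>           <int>
#> 1 strongly_unique   611
#> 2 weakly_unique       8
#> 3 non_unique        103
```

The bundled FASTA (synthetic, generated for the examples) has one random
contig and one contig containing a 25 bp tandem repeat. Of its 722 distinct
canonical 25-mers, 103 occur more than once (the repeat) and are
non-unique; 12 are weak, 8 of which are unique, leaving 611 strongly unique
25-mers. A block profile localizes the classes along the sequences:

```r
block_profile(fa, 25, cl, block_size = 250)
#> # A tibble: 5 × 7
#>   seqname              block_start block_end n_valid_starts frac_strongly_unique …
#> 1 synthetic_contig_1 …           0       250            250                0.68
#> 2 synthetic_contig_1 …         250       500            250                1
#> 3 synthetic_contig_1 …         500       600             76                1
#> 4 synthetic_contig_2 …           0       250            250                0.068
#> 5 synthetic_contig_2 …         250       500            226                0.434
```

The repeat-bearing contig is dominated by non-unique 25-mer starts, the
random contig by strongly unique ones. `autoplot()` on the profile draws
the stacked per-block fractions; `tidy(res)` returns the per-k-mer
weak/strong table.

A thin command-line wrapper is installed at
`system.file("cli/strongmark.R", package = "strongmark")` with subcommands
`mark`, `build`, `synth` and `stats` over the same functions.

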