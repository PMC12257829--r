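#include "kmer.h"
using namespace Rcpp;

// labels: 1 = strongly unique, 2 = weakly unique, 3 = non-unique
// [[Rcpp::export]]
IntegerVector classify_cpp(RawVector codes, IntegerVector counts,
                           RawVector weak, int k) {
  check_k(k);
  std::vector<uint64_t> v = raw_to_u64(codes);
  std::vector<uint64_t> w = raw_to_u64(weak);
  IntegerVector out(v.size());
  size_t wi = 0;
  for (size_t i = 0; i < v.size(); ++i) {
    while (wi < w.size() && w[wi] < v[i]) {
      // a weak code absent from the set would be skipped here: inconsistent
      stop("weak set contains a code absent from the canonical set");
    }
    bool is_weak = (wi < w.size() && w[wi] == v[i]);
    if (is_weak) ++wi;
    if (counts[i] >= 2) out[i] = 3;
    else out[i] = is_weak ? 2 : 1;
  }
  if (wi != w.size())
    stop("weak set contains a code absent from the canonical set");
  return out;
}

// Per-block class counts of k-mer start positions in one sequence.
// codes/labels: the classification map (sorted canonical codes). Returns a
// matrix with rows = blocks, columns = (n_valid, strongly, weakly, non).
// [[Rcpp::export]]
IntegerMatrix block_counts_cpp(CharacterVector seq, int k, RawVector codes,
                               IntegerVector labels, double block_size) {
  check_k(k);
  if (block_size < 1) stop("block_size must be >= 1");
  std::vector<uint64_t> v = raw_to_u64(codes);
  const char* str = CHAR(STRING_ELT(seq, 0));
  long len = (long)strlen(str);
  long nblocks = (len > 0) ? (len - 1) / (long)block_size + 1 : 0;
  IntegerMatrix out(nblocks, 4);
  uint64_t mask = code_mask(k);
  uint64_t code = 0;
  int run = 0;
  for (long i = 0; i < len; ++i) {
    int d = base_digit(str[i]);
    if (d < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)d) & mask;
    if (++run < k) continue;
    long start = i - k + 1;  // 0-based start position of this window
    uint64_t cc = canonical_u64(code, k);
    size_t lo = 0, hi = v.size();
    long hit = -1;
    while (lo < hi) {
      size_t mid = lo + (hi - lo) / 2;
      if (v[mid] < cc) lo = mid + 1;
      else if (v[mid] > cc) hi = mid;
      else { hit = (long)mid; break; }
    }
    if (hit < 0)
      stop("missing classification for a k-mer at position %ld", start + 1);
    long blk = start / (long)block_size;
    out(blk, 0) += 1;
    out(blk, labels[hit]) += 1;
  }
  return out;
}
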