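#include "kmer.h"
using namespace Rcpp;

// Count canonical k-mers in a set of sequences. Windows containing any
// non-ACGT character are skipped (the window restarts after the offending
// character). Counts saturate at 2: distinguishing "once" from "more than
// once" is all the uniqueness classification needs.
// [[Rcpp::export]]
List count_kmers_cpp(CharacterVector seqs, int k) {
  check_k(k);
  std::vector<uint64_t> all;
  uint64_t mask = code_mask(k);
  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char* str = CHAR(STRING_ELT(seqs, s));
    size_t len = strlen(str);
    uint64_t code = 0;
    int run = 0;  // length of current all-ACGT run
    for (size_t i = 0; i < len; ++i) {
      int d = base_digit(str[i]);
      if (d < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)d) & mask;
      if (++run >= k) all.push_back(canonical_u64(code, k));
    }
  }
  std::sort(all.begin(), all.end());
  std::vector<uint64_t> codes;
  std::vector<int> counts;
  for (size_t i = 0; i < all.size();) {
    size_t j = i;
    while (j < all.size() && all[j] == all[i]) ++j;
    codes.push_back(all[i]);
    counts.push_back(j - i >= 2 ? 2 : 1);
    i = j;
  }
  return List::create(_["codes"] = u64_to_raw(codes),
                      _["counts"] = IntegerVector(counts.begin(), counts.end()));
}

// Expand a canonical set into the sorted orientation-closed array of stored
// values (code << 1 | markbit, markbit initially 0). Self-reverse-
// complementary k-mers contribute a single entry.
// [[Rcpp::export]]
RawVector expand_cpp(RawVector codes, int k) {
  check_k(k);
  std::vector<uint64_t> v = raw_to_u64(codes);
  std::vector<uint64_t> out;
  out.reserve(2 * v.size());
  for (uint64_t c : v) {
    uint64_t r = rc_code_u64(c, k);
    out.push_back(c << 1);
    if (r != c) out.push_back(r << 1);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return u64_to_raw(out);
}

// Extract the expanded entries whose length-s prefix encodes integer j
// (forward and reverse-complement orientations of the canonical input set).
// [[Rcpp::export]]
RawVector extract_chunk_cpp(RawVector codes, int k, int s, double j) {
  check_k(k);
  if (s < 0 || s > k / 2) stop("s must be in [0, floor(k/2)]");
  uint64_t jj = (uint64_t)j;
  std::vector<uint64_t> v = raw_to_u64(codes);
  std::vector<uint64_t> out;
  int shift = 2 * (k - s);
  for (uint64_t c : v) {
    uint64_t r = rc_code_u64(c, k);
    if ((c >> shift) == jj) out.push_back(c << 1);
    if (r != c && (r >> shift) == jj) out.push_back(r << 1);
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  return u64_to_raw(out);
}

// Start pointers q_A, q_C, q_G, q_T, q_$ (0-based, half-open) of the
// character classes at depth d inside [start, end). The shared-prefix
// precondition (first d-1 characters equal within the interval) is not
// checked. One linear scan.
// [[Rcpp::export]]
IntegerVector subinterval_starts_cpp(RawVector stored, int k, int start,
                                     int end, int d) {
  std::vector<uint64_t> v = raw_to_u64(stored);
  if (start < 0 || end > (int)v.size() || start > end)
    stop("invalid interval [%d, %d) for array of length %d", start, end,
         (int)v.size());
  if (d < 1 || d > k) stop("depth d must be in [1, k]");
  IntegerVector q(5);
  int pos = start;
  q[0] = start;
  for (int c = 1; c <= 3; ++c) {
    while (pos < end && char_at(v[pos] >> 1, k, d) < c) ++pos;
    q[c] = pos;
  }
  q[4] = end;
  return q;
}

// Bounds of the 4^g chunks defined by the length-g prefix; 0-based half-open
// rows (start, end), row j for prefix value j.
// [[Rcpp::export]]
IntegerMatrix prefix_chunk_bounds_cpp(RawVector stored, int k, int g) {
  check_k(k);
  if (g < 0 || g > k / 2) stop("g must be in [0, floor(k/2)]");
  std::vector<uint64_t> v = raw_to_u64(stored);
  size_t nchunks = 1ULL << (2 * g);
  IntegerMatrix out(nchunks, 2);
  int shift = 2 * (k - g);
  size_t pos = 0;
  for (size_t j = 0; j < nchunks; ++j) {
    out(j, 0) = (int)pos;
    while (pos < v.size() && ((v[pos] >> 1) >> shift) == j) ++pos;
    out(j, 1) = (int)pos;
  }
  if (pos != v.size()) stop("array not sorted by code");
  return out;
}

// Invariant checks used by the R-side validators and tests.
// [[Rcpp::export]]
List check_array_cpp(RawVector stored, int k) {
  std::vector<uint64_t> v = raw_to_u64(stored);
  bool sorted = true, closed = true, distinct = true;
  for (size_t i = 1; i < v.size(); ++i) {
    if ((v[i] >> 1) < (v[i - 1] >> 1)) sorted = false;
    if ((v[i] >> 1) == (v[i - 1] >> 1)) distinct = false;
  }
  for (size_t i = 0; i < v.size() && closed; ++i) {
    uint64_t r = rc_code_u64(v[i] >> 1, k) << 1;
    // binary search on stored >> 1
    size_t lo = 0, hi = v.size();
    bool found = false;
    while (lo < hi) {
      size_t mid = (lo + hi) / 2;
      if ((v[mid] >> 1) < (r >> 1)) lo = mid + 1;
      else if ((v[mid] >> 1) > (r >> 1)) hi = mid;
      else { found = true; break; }
    }
    if (!found) closed = false;
  }
  return List::create(_["sorted"] = sorted, _["distinct"] = distinct,
                      _["closed"] = closed);
}
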