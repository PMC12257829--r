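#include "kmer.h"
using namespace Rcpp;

// ---------------------------------------------------------------------------
// shared helpers
// ---------------------------------------------------------------------------

// Distinct entries x, y at Hamming distance 1 witness weakness only when
// they are different canonical k-mers; a near-palindrome x with
// d(x, rc(x)) = 1 meets its own reverse complement in the array, which is
// the same canonical k-mer and must not count (weakness needs *another*
// member of the set).
static inline void mark_pair(std::vector<uint64_t>& A, int k, int i, int j) {
  if ((A[j] >> 1) != rc_code_u64(A[i] >> 1, k)) {
    A[i] |= 1ULL;
    A[j] |= 1ULL;
  }
}

// all-pairs bit-parallel test on [start, end); entries are distinct, so a
// passing test means Hamming distance exactly 1: mark both members.
static void pairwise_all(std::vector<uint64_t>& A, int k, int start, int end) {
  for (int i = start; i < end; ++i)
    for (int j = i + 1; j < end; ++j)
      if (hd1_u64(A[i] >> 1, A[j] >> 1)) mark_pair(A, k, i, j);
}

// binary search for a code in the stored array (mark bits ignored)
static long find_code(const std::vector<uint64_t>& A, uint64_t code) {
  size_t lo = 0, hi = A.size();
  while (lo < hi) {
    size_t mid = lo + (hi - lo) / 2;
    uint64_t c = A[mid] >> 1;
    if (c < code) lo = mid + 1;
    else if (c > code) hi = mid;
    else return (long)mid;
  }
  return -1;
}

// ---------------------------------------------------------------------------
// FourWay
// ---------------------------------------------------------------------------

struct Frame { int q[5]; int d; };

static Frame scan_frame(const std::vector<uint64_t>& A, int k, int start,
                        int end, int d) {
  Frame f;
  f.d = d;
  int pos = start;
  f.q[0] = start;
  for (int c = 1; c <= 3; ++c) {
    while (pos < end && char_at(A[pos] >> 1, k, d) < c) ++pos;
    f.q[c] = pos;
  }
  f.q[4] = end;
  return f;
}

// One 4-way merge-style pass over an interval whose first d-1 characters are
// equal: cursors walk the four character classes in parallel; whenever two or
// more cursors hold the same minimal (k-d)-suffix, those k-mers differ only
// at position d and are marked weak.
static void fourway_pass(std::vector<uint64_t>& A, int k, const Frame& f) {
  int d = f.d, b = k - d;
  uint64_t sufmask = (b > 0) ? ((1ULL << (2 * b)) - 1ULL) : 0ULL;
  int p[4];
  bool act[4];
  int nact = 0;
  for (int c = 0; c < 4; ++c) {
    p[c] = f.q[c];
    act[c] = p[c] < f.q[c + 1];
    if (act[c]) ++nact;
  }
  while (nact >= 2) {
    uint64_t best = 0;
    int v = 0;  // 4-bit minimal-set vector, A=1 C=2 G=4 T=8
    for (int c = 0; c < 4; ++c) {
      if (!act[c]) continue;
      uint64_t s = (A[p[c]] >> 1) & sufmask;
      if (v == 0 || s < best) { best = s; v = 1 << c; }
      else if (s == best) v |= 1 << c;
    }
    if (v & (v - 1)) {  // |C*| >= 2: candidate weak group
      for (int c1 = 0; c1 < 4; ++c1) {
        if (!((v >> c1) & 1)) continue;
        for (int c2 = c1 + 1; c2 < 4; ++c2)
          if ((v >> c2) & 1) mark_pair(A, k, p[c1], p[c2]);
      }
    }
    for (int c = 0; c < 4; ++c) {
      if (!((v >> c) & 1)) continue;
      if (++p[c] >= f.q[c + 1]) { act[c] = false; --nact; }
    }
  }
}

// Iterative recursion over sub-intervals with an explicit stack; intervals of
// length <= tau are handled by direct pairwise testing (tau = 1 disables the
// hybrid since length-1 intervals need no work anyway).
static void fourway_interval_run(std::vector<uint64_t>& A, int k, int start,
                                 int end, int d0, int tau) {
  if (end - start <= 1) return;
  if (end - start <= tau) { pairwise_all(A, k, start, end); return; }
  std::vector<Frame> stack;
  stack.push_back(scan_frame(A, k, start, end, d0));
  while (!stack.empty()) {
    Frame f = stack.back();
    stack.pop_back();
    fourway_pass(A, k, f);
    if (f.d >= k) continue;
    for (int c = 0; c < 4; ++c) {
      int s = f.q[c], e = f.q[c + 1];
      if (e - s <= 1) continue;
      if (e - s <= tau) pairwise_all(A, k, s, e);
      else stack.push_back(scan_frame(A, k, s, e, f.d + 1));
    }
  }
}

// [[Rcpp::export]]
RawVector fourway_interval_cpp(RawVector stored, int k, int start, int end,
                               int d, int tau) {
  check_k(k);
  std::vector<uint64_t> A = raw_to_u64(stored);
  if (start < 0 || end > (int)A.size() || start > end) stop("invalid interval");
  if (tau < 1) stop("tau must be >= 1");
  if (d < 1 || d > k) stop("depth d must be in [1, k]");
  fourway_interval_run(A, k, start, end, d, tau);
  return u64_to_raw(A);
}

// FourWay over one array range: partition into maximal blocks sharing the
// floor(k/2)-prefix (one linear scan), then run the recursion inside each
// block starting at depth floor(k/2)+1. With full_depth, the whole range is
// processed from depth 1 (testing variant; requires the range to be the
// whole array).
static void fourway_range(std::vector<uint64_t>& A, int k, int start, int end,
                          int tau, bool full_depth) {
  if (full_depth) {
    fourway_interval_run(A, k, start, end, 1, tau);
    return;
  }
  int hb = k / 2;
  int shift = 2 * (k - hb);
  int i = start;
  while (i < end) {
    int j = i + 1;
    while (j < end && ((A[j] >> 1) >> shift) == ((A[i] >> 1) >> shift)) ++j;
    if (j - i >= 2) fourway_interval_run(A, k, i, j, hb + 1, tau);
    i = j;
  }
}

// ---------------------------------------------------------------------------
// Quarter
// ---------------------------------------------------------------------------

static inline uint64_t swap_sections_u64(uint64_t code, int s1, int s2) {
  uint64_t pre = code >> (2 * (s1 + s2));
  uint64_t a = (code >> (2 * s2)) & code_mask(s1);
  uint64_t b = code & code_mask(s2);
  return (pre << (2 * (s1 + s2))) | (b << (2 * s1)) | a;
}

// [[Rcpp::export]]
NumericVector swap_sections_cpp(NumericVector codes, int k, int s1, int s2) {
  if (s1 + s2 > k || s1 < 0 || s2 < 0) stop("invalid section lengths");
  NumericVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    double x = codes[i];
    if (x < 0 || x != std::floor(x)) stop("invalid code");
    out[i] = (double)swap_sections_u64((uint64_t)x, s1, s2);
  }
  return out;
}

static void bucket_pass(std::vector<uint64_t>& A, int k, int start, int end,
                        int prefix_len) {
  int shift = 2 * (k - prefix_len);
  int i = start;
  while (i < end) {
    int j = i + 1;
    while (j < end && ((A[j] >> 1) >> shift) == ((A[i] >> 1) >> shift)) ++j;
    if (j - i >= 2) pairwise_all(A, k, i, j);
    i = j;
  }
}

// [[Rcpp::export]]
RawVector bucket_pairwise_pass_cpp(RawVector stored, int k, int prefix_len) {
  check_k(k);
  if (prefix_len < 0 || prefix_len > k) stop("invalid prefix length");
  std::vector<uint64_t> A = raw_to_u64(stored);
  bucket_pass(A, k, 0, (int)A.size(), prefix_len);
  return u64_to_raw(A);
}

// Quarter over one array range. Phase 1 buckets by the (ell + s1)-prefix and
// catches single differences in the last quarter s2. Phase 2 works within
// each maximal ell-prefix block on a scratch copy with the s1/s2 sections
// swapped (carrying original indices), re-sorted, bucketed by the swapped
// (ell + s2)-prefix; marks map back positionally.
static void quarter_range(std::vector<uint64_t>& A, int k, int start, int end) {
  int ell = k / 2;
  int r = k - ell;
  int s1 = (r + 1) / 2, s2 = r / 2;
  bucket_pass(A, k, start, end, ell + s1);

  int shift_ell = 2 * (k - ell);
  int shift_p2 = 2 * s1;  // swapped (ell + s2)-prefix
  std::vector<std::pair<uint64_t, int> > blk;
  int i = start;
  while (i < end) {
    int j = i + 1;
    while (j < end && ((A[j] >> 1) >> shift_ell) == ((A[i] >> 1) >> shift_ell))
      ++j;
    if (j - i >= 2) {
      blk.clear();
      blk.reserve(j - i);
      for (int t = i; t < j; ++t)
        blk.push_back(std::make_pair(swap_sections_u64(A[t] >> 1, s1, s2), t));
      std::sort(blk.begin(), blk.end());
      size_t a = 0;
      while (a < blk.size()) {
        size_t b = a + 1;
        while (b < blk.size() &&
               (blk[b].first >> shift_p2) == (blk[a].first >> shift_p2))
          ++b;
        for (size_t x = a; x < b; ++x)
          for (size_t y = x + 1; y < b; ++y)
            if (hd1_u64(blk[x].first, blk[y].first))
              mark_pair(A, k, blk[x].second, blk[y].second);
        a = b;
      }
    }
    i = j;
  }
}

// ---------------------------------------------------------------------------
// range dispatcher (chunk scheduling contract: any order, disjoint slices)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
RawVector mark_ranges_cpp(RawVector stored, int k, std::string algorithm,
                          int tau, IntegerMatrix ranges, bool full_depth) {
  check_k(k);
  std::vector<uint64_t> A = raw_to_u64(stored);
  if (tau < 1) stop("tau must be >= 1");
  for (int r = 0; r < ranges.nrow(); ++r) {
    int s = ranges(r, 0), e = ranges(r, 1);
    if (s < 0 || e > (int)A.size() || s > e) stop("invalid chunk range");
    if (algorithm == "fourway") {
      fourway_range(A, k, s, e, tau, full_depth);
    } else if (algorithm == "quarter") {
      if (k < 4) stop("quarter requires k >= 4");
      quarter_range(A, k, s, e);
    } else {
      stop("unknown algorithm '%s'", algorithm.c_str());
    }
  }
  return u64_to_raw(A);
}

// ---------------------------------------------------------------------------
// orientation propagation
// ---------------------------------------------------------------------------

// A marking pass only finds the orientation pair whose difference lies in the
// processed positions; a k-mer is weak iff it or its reverse complement is
// marked. Returns the sorted set of weak canonical codes.
// With check_closure (the whole-array case), a marked entry whose reverse
// complement is absent is a corrupted array; prefix chunks of a split input
// are not orientation-closed, so the check is skipped for them.
// [[Rcpp::export]]
RawVector propagate_cpp(RawVector stored, int k, bool check_closure) {
  check_k(k);
  std::vector<uint64_t> A = raw_to_u64(stored);
  std::vector<uint64_t> weak;
  for (size_t i = 0; i < A.size(); ++i) {
    if (!(A[i] & 1ULL)) continue;
    uint64_t c = A[i] >> 1;
    uint64_t r = rc_code_u64(c, k);
    if (check_closure && r != c && find_code(A, r) < 0)
      stop("corrupted array: reverse complement of a marked entry is missing");
    weak.push_back(c > r ? c : r);
  }
  std::sort(weak.begin(), weak.end());
  weak.erase(std::unique(weak.begin(), weak.end()), weak.end());
  return u64_to_raw(weak);
}

// ---------------------------------------------------------------------------
// naive baseline oracles
// ---------------------------------------------------------------------------

// Full pairwise comparison over the canonical set: test all n(n-1)/2 pairs
// for canonical Hamming distance <= 1 (distinct canonical codes cannot be at
// distance 0). Returns the weak canonical codes and the number of pair tests.
// [[Rcpp::export]]
List full_pairwise_cpp(RawVector codes, int k) {
  check_k(k);
  std::vector<uint64_t> v = raw_to_u64(codes);
  size_t n = v.size();
  std::vector<uint64_t> rc(n);
  for (size_t i = 0; i < n; ++i) rc[i] = rc_code_u64(v[i], k);
  std::vector<bool> weak(n, false);
  double tests = 0;
  for (size_t i = 0; i < n; ++i)
    for (size_t j = i + 1; j < n; ++j) {
      ++tests;
      if (hd1_u64(v[i], v[j]) || hd1_u64(v[i], rc[j])) {
        weak[i] = true;
        weak[j] = true;
      }
    }
  std::vector<uint64_t> out;
  for (size_t i = 0; i < n; ++i)
    if (weak[i]) out.push_back(v[i]);
  std::sort(out.begin(), out.end());
  return List::create(_["weak"] = u64_to_raw(out), _["n_tests"] = tests);
}

// Neighborhood generation over the canonical set (must be sorted): for each
// member, generate the canonical codes of its 3k Hamming-distance-1
// neighbours and look them up; every hit marks both. A generated neighbour
// may canonicalize back onto its origin (when it equals rc of the origin);
// such self-hits are not weakness. With early_exit (baseline-benchmark mode),
// members already marked are skipped and search stops at the first hit.
// [[Rcpp::export]]
RawVector neighborhood_cpp(RawVector codes, int k, bool early_exit) {
  check_k(k);
  std::vector<uint64_t> v = raw_to_u64(codes);
  size_t n = v.size();
  for (size_t i = 1; i < n; ++i)
    if (v[i] <= v[i - 1]) stop("canonical codes must be sorted and distinct");
  std::vector<bool> weak(n, false);
  for (size_t i = 0; i < n; ++i) {
    if (early_exit && weak[i]) continue;
    uint64_t x = v[i];
    bool done = false;
    for (int pos = 1; pos <= k && !done; ++pos) {
      int shift = 2 * (k - pos);
      int cur = (int)((x >> shift) & 3ULL);
      for (int d = 0; d < 4; ++d) {
        if (d == cur) continue;
        uint64_t y = (x & ~(3ULL << shift)) | ((uint64_t)d << shift);
        uint64_t cy = canonical_u64(y, k);
        if (cy == x) continue;
        size_t lo = 0, hi = n;
        long hit = -1;
        while (lo < hi) {
          size_t mid = lo + (hi - lo) / 2;
          if (v[mid] < cy) lo = mid + 1;
          else if (v[mid] > cy) hi = mid;
          else { hit = (long)mid; break; }
        }
        if (hit >= 0) {
          weak[i] = true;
          weak[hit] = true;
          if (early_exit) { done = true; break; }
        }
      }
    }
  }
  std::vector<uint64_t> out;
  for (size_t i = 0; i < n; ++i)
    if (weak[i]) out.push_back(v[i]);
  return u64_to_raw(out);
}
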