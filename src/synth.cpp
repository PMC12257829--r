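#include "kmer.h"
#include <unordered_set>
using namespace Rcpp;

// All randomness flows through R's RNG (RNGScope via Rcpp attributes), so
// set.seed() / withr::with_seed() on the R side fully determine the output.

static inline int rand_digit() { return (int)(unif_rand() * 4.0) & 3; }

static uint64_t rand_code(int k) {
  uint64_t c = 0;
  for (int i = 0; i < k; ++i) c = (c << 2) | (uint64_t)rand_digit();
  return c;
}

// number of distinct canonical k-mers: (4^k + #palindromes) / 2,
// palindromes exist only for even k (2^k of them)
static double canonical_capacity(int k) {
  double total = std::pow(4.0, k);
  double pal = (k % 2 == 0) ? std::pow(2.0, k) : 0.0;
  return (total + pal) / 2.0;
}

// [[Rcpp::export]]
List gen_random_cpp(double n, int k, double p_count2) {
  check_k(k);
  if (n < 0 || n != std::floor(n)) stop("n must be a non-negative integer");
  if (n > canonical_capacity(k))
    stop("infeasible: n = %.0f exceeds the %.0f distinct canonical %d-mers",
         n, canonical_capacity(k), k);
  std::unordered_set<uint64_t> seen;
  std::vector<uint64_t> codes;
  codes.reserve((size_t)n);
  long guard = 0;
  while ((double)codes.size() < n) {
    if (++guard > 1000 * (long)(n + 64))
      stop("rejection sampling failed to reach n distinct canonical codes");
    uint64_t c = canonical_u64(rand_code(k), k);
    if (seen.insert(c).second) codes.push_back(c);
  }
  std::sort(codes.begin(), codes.end());
  IntegerVector counts(codes.size());
  for (size_t i = 0; i < codes.size(); ++i)
    counts[i] = (p_count2 > 0 && unif_rand() < p_count2) ? 2 : 1;
  return List::create(_["codes"] = u64_to_raw(codes), _["counts"] = counts);
}

// Build the orientation-closed entry group {x, rc(x), y, rc(y)} of a random
// code x and its Hamming-distance-1 neighbour y (one position replaced by
// its complement). Group size is 4, or 3 if one member is palindromic.
// Degenerate draws with y == rc(x) (the "pair" would be a single canonical
// k-mer) are rejected by returning an empty group.
static void make_weak_group(int k, std::vector<uint64_t>& grp) {
  grp.clear();
  uint64_t x = rand_code(k);
  int pos = (int)(unif_rand() * k);
  if (pos >= k) pos = k - 1;
  int shift = 2 * (k - 1 - pos);
  int cur = (int)((x >> shift) & 3ULL);
  uint64_t y = (x & ~(3ULL << shift)) | ((uint64_t)(3 - cur) << shift);
  uint64_t rx = rc_code_u64(x, k), ry = rc_code_u64(y, k);
  if (y == rx) return;
  grp.push_back(x);
  if (rx != x) grp.push_back(rx);
  if (y != x && y != rx) grp.push_back(y);
  if (ry != y && ry != x && ry != rx) grp.push_back(ry);
}

// [[Rcpp::export]]
RawVector gen_all_weak_cpp(double n, int k) {
  check_k(k);
  if (n < 2 || n != std::floor(n)) stop("n must be an integer >= 2");
  if (2.0 * n > std::pow(4.0, k))
    stop("infeasible: n = %.0f too large for k = %d", n, k);
  // n = 4a + 3b: b size-3 groups (palindromic member) are needed only when
  // n is not divisible by 4; such groups are rare (even k only)
  int b = (int)((3 * ((long)n % 4)) % 4);
  long a = ((long)n - 3L * b) / 4L;
  if (a < 0) stop("infeasible: n = %.0f cannot be written as 4a + 3b", n);

  std::unordered_set<uint64_t> used;
  std::vector<uint64_t> out;
  out.reserve((size_t)n);
  std::vector<uint64_t> grp;
  long need3 = b, need4 = a, guard = 0;
  while (need3 > 0 || need4 > 0) {
    if (++guard > 200 * (long)(n + 64))
      stop("infeasible: could not assemble %.0f entries from weak pair groups%s",
           n, (b > 0) ? " (sizes not divisible by 4 need rare palindromic groups)"
                      : "");
    make_weak_group(k, grp);
    if (grp.empty()) continue;
    long* need = (grp.size() == 4) ? &need4 : (grp.size() == 3 ? &need3 : 0);
    if (!need || *need <= 0) continue;
    bool fresh = true;
    for (uint64_t e : grp)
      if (used.count(e)) { fresh = false; break; }
    if (!fresh) continue;
    for (uint64_t e : grp) {
      used.insert(e);
      out.push_back(e << 1);
    }
    --*need;
  }
  std::sort(out.begin(), out.end());
  return u64_to_raw(out);
}

// helper for gen_all_strong (R side drives oversampling retries): draw m
// distinct canonical codes, return raw
// [[Rcpp::export]]
RawVector draw_canonical_cpp(double m, int k) {
  List l = gen_random_cpp(m, k, 0.0);
  return l["codes"];
}

// From strong canonical codes (sorted raw), pick entries to reach exactly n
// expanded entries: n even -> n/2 non-palindromic codes; n odd -> one
// palindromic code plus (n-1)/2 non-palindromic ones. Returns an empty raw
// vector if not enough suitable codes survive (caller retries larger draws).
// [[Rcpp::export]]
RawVector assemble_strong_cpp(RawVector codes, int k, double n) {
  check_k(k);
  std::vector<uint64_t> v = raw_to_u64(codes);
  long need_pal = ((long)n % 2 == 1) ? 1 : 0;
  long need_np = ((long)n - need_pal) / 2;
  std::vector<uint64_t> out;
  out.reserve((size_t)n);
  for (uint64_t c : v) {
    uint64_t r = rc_code_u64(c, k);
    if (r == c) {
      if (need_pal > 0) { out.push_back(c << 1); --need_pal; }
    } else if (need_np > 0) {
      out.push_back(c << 1);
      out.push_back(r << 1);
      --need_np;
    }
    if (need_pal == 0 && need_np == 0) break;
  }
  if (need_pal != 0 || need_np != 0) return RawVector(0);
  std::sort(out.begin(), out.end());
  return u64_to_raw(out);
}
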