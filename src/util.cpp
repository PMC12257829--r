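#include "kmer.h"
using namespace Rcpp;

// canonicalize, sort, and aggregate (saturating counts at 2) an arbitrary
// collection of codes with per-code counts
// [[Rcpp::export]]
List make_kset_cpp(RawVector codes, IntegerVector counts, int k) {
  check_k(k);
  std::vector<uint64_t> v = raw_to_u64(codes);
  if ((R_xlen_t)v.size() != counts.size())
    stop("codes and counts lengths differ");
  std::vector<std::pair<uint64_t, int> > pairs(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int ct = counts[i];
    if (ct < 1) stop("counts must be >= 1");
    pairs[i] = std::make_pair(canonical_u64(v[i], k), ct > 2 ? 2 : ct);
  }
  std::sort(pairs.begin(), pairs.end());
  std::vector<uint64_t> out;
  std::vector<int> cts;
  for (size_t i = 0; i < pairs.size();) {
    size_t j = i;
    long tot = 0;
    while (j < pairs.size() && pairs[j].first == pairs[i].first)
      tot += pairs[j++].second;
    out.push_back(pairs[i].first);
    cts.push_back(tot >= 2 ? 2 : 1);
    i = j;
  }
  return List::create(_["codes"] = u64_to_raw(out),
                      _["counts"] = IntegerVector(cts.begin(), cts.end()));
}

// canonical representatives present in an expanded array: entries whose code
// equals its own canonical code (sorted input stays sorted when filtered)
// [[Rcpp::export]]
RawVector array_canonical_cpp(RawVector stored, int k) {
  check_k(k);
  std::vector<uint64_t> v = raw_to_u64(stored);
  std::vector<uint64_t> out;
  for (uint64_t s : v) {
    uint64_t c = s >> 1;
    if (c >= rc_code_u64(c, k)) out.push_back(c);
  }
  return u64_to_raw(out);
}

// set difference a \ b on sorted uint64 payloads
// [[Rcpp::export]]
RawVector raw_setdiff_cpp(RawVector a, RawVector b) {
  std::vector<uint64_t> x = raw_to_u64(a), y = raw_to_u64(b), out;
  std::set_difference(x.begin(), x.end(), y.begin(), y.end(),
                      std::back_inserter(out));
  return u64_to_raw(out);
}

// set union on sorted uint64 payloads
// [[Rcpp::export]]
RawVector raw_union_cpp(RawVector a, RawVector b) {
  std::vector<uint64_t> x = raw_to_u64(a), y = raw_to_u64(b), out;
  std::set_union(x.begin(), x.end(), y.begin(), y.end(),
                 std::back_inserter(out));
  return u64_to_raw(out);
}

// membership of sorted payload b entries in sorted payload a
// [[Rcpp::export]]
LogicalVector raw_in_cpp(RawVector b, RawVector a) {
  std::vector<uint64_t> x = raw_to_u64(a), y = raw_to_u64(b);
  LogicalVector out(y.size());
  for (size_t i = 0; i < y.size(); ++i)
    out[i] = std::binary_search(x.begin(), x.end(), y[i]);
  return out;
}

// 1-based order permutation sorting a uint64 payload ascending
// [[Rcpp::export]]
IntegerVector raw_order_cpp(RawVector a) {
  std::vector<uint64_t> x = raw_to_u64(a);
  std::vector<int> idx(x.size());
  for (size_t i = 0; i < x.size(); ++i) idx[i] = (int)i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&x](int i, int j) { return x[i] < x[j]; });
  IntegerVector out(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) out[i] = idx[i] + 1;
  return out;
}

// reorder a uint64 payload by a 1-based index permutation
// [[Rcpp::export]]
RawVector raw_subset_cpp(RawVector a, IntegerVector idx) {
  std::vector<uint64_t> x = raw_to_u64(a), out(idx.size());
  for (R_xlen_t i = 0; i < idx.size(); ++i) {
    int j = idx[i] - 1;
    if (j < 0 || j >= (int)x.size()) stop("index out of range");
    out[i] = x[j];
  }
  return u64_to_raw(out);
}

// (code << 1 | mark) for each code of a payload
// [[Rcpp::export]]
RawVector raw_shift_mark_cpp(RawVector codes, bool mark) {
  std::vector<uint64_t> v = raw_to_u64(codes);
  for (size_t i = 0; i < v.size(); ++i)
    v[i] = (v[i] << 1) | (mark ? 1ULL : 0ULL);
  return u64_to_raw(v);
}

// drop the mark bit: stored >> 1
// [[Rcpp::export]]
RawVector raw_unshift_cpp(RawVector stored) {
  std::vector<uint64_t> v = raw_to_u64(stored);
  for (size_t i = 0; i < v.size(); ++i) v[i] >>= 1;
  return u64_to_raw(v);
}
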