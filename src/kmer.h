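#ifndef STRONGMARK_KMER_H
#define STRONGMARK_KMER_H

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

// 2-bit encoding: A=0, C=1, G=2, T=3 (lexicographic); first character of the
// k-mer is the most significant base-4 digit. A k-mer code occupies the low
// 2k bits of a uint64_t; k <= 31 so at least one bit is free for marking.

static const uint64_t EVEN_MASK = 0x5555555555555555ULL;

inline int base_digit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char digit_base(int d) {
  static const char b[4] = {'A', 'C', 'G', 'T'};
  return b[d & 3];
}

inline uint64_t code_mask(int k) {
  return (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
}

// reverse complement on the integer code: complement = bitwise NOT
// (A=00 <-> T=11, C=01 <-> G=10), reversal = reversal of 2-bit groups.
inline uint64_t rc_code_u64(uint64_t code, int k) {
  uint64_t x = ~code;
  x = ((x & 0x3333333333333333ULL) << 2) | ((x >> 2) & 0x3333333333333333ULL);
  x = ((x & 0x0F0F0F0F0F0F0F0FULL) << 4) | ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL);
  x = ((x & 0x00FF00FF00FF00FFULL) << 8) | ((x >> 8) & 0x00FF00FF00FF00FFULL);
  x = ((x & 0x0000FFFF0000FFFFULL) << 16) | ((x >> 16) & 0x0000FFFF0000FFFFULL);
  x = (x << 32) | (x >> 32);
  return x >> (64 - 2 * k);
}

inline uint64_t canonical_u64(uint64_t code, int k) {
  uint64_t r = rc_code_u64(code, k);
  return code > r ? code : r;
}

// bit-parallel Hamming distance: u = p XOR q; fold each 2-bit group onto its
// even bit; popcount of the folded mask is the number of differing positions.
inline int hamming_u64(uint64_t p, uint64_t q) {
  uint64_t u = p ^ q;
  uint64_t h = (u | (u >> 1)) & EVEN_MASK;
  return __builtin_popcountll(h);
}

// distance <= 1 iff the folded mask h has at most one set bit: h & (h-1) == 0.
inline bool hd1_u64(uint64_t p, uint64_t q) {
  uint64_t u = p ^ q;
  uint64_t h = (u | (u >> 1)) & EVEN_MASK;
  return (h & (h - 1)) == 0;
}

inline int canonical_hamming_u64(uint64_t x, uint64_t y, int k) {
  int d1 = hamming_u64(x, y);
  int d2 = hamming_u64(x, rc_code_u64(y, k));
  return d1 < d2 ? d1 : d2;
}

inline bool chd1_u64(uint64_t x, uint64_t y, int k) {
  return hd1_u64(x, y) || hd1_u64(x, rc_code_u64(y, k));
}

// encode a string k-mer; returns false on a non-ACGT character
inline bool encode_u64(const char* s, int k, uint64_t& out) {
  uint64_t code = 0;
  for (int i = 0; i < k; ++i) {
    int d = base_digit(s[i]);
    if (d < 0) return false;
    code = (code << 2) | (uint64_t)d;
  }
  out = code;
  return true;
}

inline std::string decode_u64(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = digit_base((int)(code & 3ULL));
    code >>= 2;
  }
  return s;
}

// 1-based character extraction: position 1 is the most significant digit
inline int char_at(uint64_t code, int k, int pos) {
  return (int)((code >> (2 * (k - pos))) & 3ULL);
}

// raw vector (little-endian packed uint64) <-> std::vector<uint64_t>
inline std::vector<uint64_t> raw_to_u64(const Rcpp::RawVector& r) {
  if (r.size() % 8 != 0)
    Rcpp::stop("raw payload length must be a multiple of 8 bytes");
  size_t n = r.size() / 8;
  std::vector<uint64_t> v(n);
  for (size_t i = 0; i < n; ++i) {
    uint64_t x = 0;
    for (int j = 7; j >= 0; --j) x = (x << 8) | (uint64_t)r[8 * i + j];
    v[i] = x;
  }
  return v;
}

inline Rcpp::RawVector u64_to_raw(const std::vector<uint64_t>& v) {
  Rcpp::RawVector r(8 * v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint64_t x = v[i];
    for (int j = 0; j < 8; ++j) {
      r[8 * i + j] = (Rbyte)(x & 0xFF);
      x >>= 8;
    }
  }
  return r;
}

inline void check_k(int k, int kmin = 2) {
  if (k < kmin || k > 31)
    Rcpp::stop("k must be between %d and 31 (got %d)", kmin, k);
}

#endif
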