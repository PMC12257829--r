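#include "kmer.h"
using namespace Rcpp;

// Numeric codes cross the R boundary as doubles. A double holds integers
// exactly up to 2^53, i.e. codes for k <= 26; the R wrappers enforce that
// limit. The string interfaces and the raw-backed array pipeline are exact
// for all k <= 31.

static uint64_t num_to_code(double x, int k) {
  if (ISNAN(x) || x < 0 || x != std::floor(x))
    stop("k-mer code must be a non-negative integer value");
  uint64_t c = (uint64_t)x;
  if (k < 32 && c >= (1ULL << (2 * k)))
    stop("k-mer code %.0f out of range for k = %d (must be < 4^k)", x, k);
  return c;
}

// [[Rcpp::export]]
NumericVector encode_cpp(CharacterVector seqs, int k) {
  check_k(k);
  NumericVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    if ((int)strlen(s) != k)
      stop("sequence %d has length %d, expected k = %d", (int)(i + 1),
           (int)strlen(s), k);
    uint64_t code;
    if (!encode_u64(s, k, code))
      stop("sequence '%s' contains a non-ACGT character", s);
    out[i] = (double)code;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector decode_cpp(NumericVector codes, int k) {
  check_k(k);
  CharacterVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = decode_u64(num_to_code(codes[i], k), k);
  return out;
}

// [[Rcpp::export]]
NumericVector rc_code_cpp(NumericVector codes, int k) {
  check_k(k);
  NumericVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = (double)rc_code_u64(num_to_code(codes[i], k), k);
  return out;
}

// [[Rcpp::export]]
NumericVector canonical_code_cpp(NumericVector codes, int k) {
  check_k(k);
  NumericVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = (double)canonical_u64(num_to_code(codes[i], k), k);
  return out;
}

// [[Rcpp::export]]
IntegerVector hamming_cpp(NumericVector p, NumericVector q, int k) {
  check_k(k);
  R_xlen_t n = std::max(p.size(), q.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = hamming_u64(num_to_code(p[i % p.size()], k),
                         num_to_code(q[i % q.size()], k));
  return out;
}

// [[Rcpp::export]]
LogicalVector hd_at_most_1_cpp(NumericVector p, NumericVector q, int k) {
  check_k(k);
  R_xlen_t n = std::max(p.size(), q.size());
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = hd1_u64(num_to_code(p[i % p.size()], k),
                     num_to_code(q[i % q.size()], k));
  return out;
}

// [[Rcpp::export]]
IntegerVector canonical_hamming_cpp(NumericVector x, NumericVector y, int k) {
  check_k(k);
  R_xlen_t n = std::max(x.size(), y.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = canonical_hamming_u64(num_to_code(x[i % x.size()], k),
                                   num_to_code(y[i % y.size()], k), k);
  return out;
}

// ---- string interfaces: exact for all k <= 31 ----

static uint64_t encode_checked(const char* s, int& k) {
  k = (int)strlen(s);
  check_k(k);
  uint64_t code;
  if (!encode_u64(s, k, code))
    stop("sequence '%s' contains a non-ACGT character", s);
  return code;
}

// [[Rcpp::export]]
CharacterVector rc_str_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    int k;
    uint64_t c = encode_checked(CHAR(STRING_ELT(seqs, i)), k);
    out[i] = decode_u64(rc_code_u64(c, k), k);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector canonical_str_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    int k;
    uint64_t c = encode_checked(CHAR(STRING_ELT(seqs, i)), k);
    out[i] = decode_u64(canonical_u64(c, k), k);
  }
  return out;
}

static void check_same_k(int kx, int ky) {
  if (kx != ky)
    stop("k-mers have different lengths (%d vs %d)", kx, ky);
}

// [[Rcpp::export]]
IntegerVector hamming_str_cpp(CharacterVector x, CharacterVector y) {
  R_xlen_t n = std::max(x.size(), y.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int kx, ky;
    uint64_t p = encode_checked(CHAR(STRING_ELT(x, i % x.size())), kx);
    uint64_t q = encode_checked(CHAR(STRING_ELT(y, i % y.size())), ky);
    check_same_k(kx, ky);
    out[i] = hamming_u64(p, q);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector hd_at_most_1_str_cpp(CharacterVector x, CharacterVector y) {
  R_xlen_t n = std::max(x.size(), y.size());
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int kx, ky;
    uint64_t p = encode_checked(CHAR(STRING_ELT(x, i % x.size())), kx);
    uint64_t q = encode_checked(CHAR(STRING_ELT(y, i % y.size())), ky);
    check_same_k(kx, ky);
    out[i] = hd1_u64(p, q);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector canonical_hamming_str_cpp(CharacterVector x, CharacterVector y) {
  R_xlen_t n = std::max(x.size(), y.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int kx, ky;
    uint64_t p = encode_checked(CHAR(STRING_ELT(x, i % x.size())), kx);
    uint64_t q = encode_checked(CHAR(STRING_ELT(y, i % y.size())), ky);
    check_same_k(kx, ky);
    out[i] = canonical_hamming_u64(p, q, kx);
  }
  return out;
}

// ---- raw <-> string / numeric bridges used by the R containers ----

// [[Rcpp::export]]
CharacterVector raw_decode_cpp(RawVector codes, int k, bool drop_markbit) {
  std::vector<uint64_t> v = raw_to_u64(codes);
  CharacterVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i)
    out[i] = decode_u64(drop_markbit ? (v[i] >> 1) : v[i], k);
  return out;
}

// [[Rcpp::export]]
RawVector str_to_raw_codes_cpp(CharacterVector seqs, int k) {
  check_k(k);
  std::vector<uint64_t> v(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    if ((int)strlen(s) != k)
      stop("sequence %d has length %d, expected k = %d", (int)(i + 1),
           (int)strlen(s), k);
    if (!encode_u64(s, k, v[i]))
      stop("sequence '%s' contains a non-ACGT character", s);
  }
  return u64_to_raw(v);
}

// [[Rcpp::export]]
NumericVector raw_to_num_cpp(RawVector codes) {
  std::vector<uint64_t> v = raw_to_u64(codes);
  NumericVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = (double)v[i];
  return out;
}

// [[Rcpp::export]]
LogicalVector raw_markbits_cpp(RawVector stored) {
  std::vector<uint64_t> v = raw_to_u64(stored);
  LogicalVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = (v[i] & 1ULL) != 0;
  return out;
}
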