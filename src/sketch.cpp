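// k-mer bottom sketches and containment estimation.
#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// splitmix64: decorrelates the 2-bit k-mer code from its hash rank
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Bottom-s sketch of distinct canonical k-mers; hashes truncated to 53 bits
// so they are exactly representable as doubles on the R side.
// [[Rcpp::export]]
NumericVector cpp_sketch(const std::string& seq, int k, int sketch_size) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  std::unordered_set<uint64_t> seen;
  seen.reserve(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++valid >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      seen.insert(splitmix64(canon) >> 11);
    }
  }
  std::vector<uint64_t> h(seen.begin(), seen.end());
  std::sort(h.begin(), h.end());
  size_t s = std::min((size_t)sketch_size, h.size());
  NumericVector out(s);
  for (size_t i = 0; i < s; ++i) out[i] = (double)h[i];
  return out;
}

static int sorted_intersect_size(const NumericVector& a, const NumericVector& b) {
  int i = 0, j = 0, n = 0;
  const int na = a.size(), nb = b.size();
  while (i < na && j < nb) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}

// [[Rcpp::export]]
int cpp_sorted_intersect(NumericVector a, NumericVector b) {
  return sorted_intersect_size(a, b);
}

// Symmetric matrix of |S_a n S_b| / min(|S_a|, |S_b|) over a list of sketches.
// [[Rcpp::export]]
NumericMatrix cpp_containment_matrix(List sketches) {
  const int n = sketches.size();
  std::vector<NumericVector> sk(n);
  for (int i = 0; i < n; ++i) sk[i] = as<NumericVector>(sketches[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = sk[i].size() > 0 ? 1.0 : NA_REAL;
    for (int j = i + 1; j < n; ++j) {
      double denom = std::min(sk[i].size(), sk[j].size());
      double v = denom > 0 ? sorted_intersect_size(sk[i], sk[j]) / denom : NA_REAL;
      out(i, j) = v;
      out(j, i) = v;
    }
  }
  return out;
}
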