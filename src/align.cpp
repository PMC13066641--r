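// Banded match-count alignment used for protein-family clustering and
// unequal-length LTR pair comparison.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Maximum number of matched characters in a global alignment of a and b in
// which insertions/deletions are free but restricted to a band around the
// main diagonal (band half-width = |len(a)-len(b)| + band). Equivalent to a
// banded longest common subsequence.
// [[Rcpp::export]]
int cpp_banded_matches(const std::string& a, const std::string& b, int band) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0;
  const int w = std::abs(n - m) + band;
  // dp over j in [max(0, i-w), min(m, i+w)]
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i - w), jhi = std::min(m, i + w);
    if (jlo > 1) cur[jlo - 1] = 0;
    for (int j = jlo; j <= jhi; ++j) {
      int best = 0;
      if (j - 1 >= i - w - 1) best = std::max(best, cur[j - 1]);
      if (j <= i - 1 + w) best = std::max(best, prev[j]);
      int d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 1 : 0);
      best = std::max(best, d);
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
int cpp_hamming(const std::string& a, const std::string& b) {
  if (a.size() != b.size()) stop("sequences must have equal length");
  int d = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
  return d;
}
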