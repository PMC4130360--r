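#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Smith-Waterman local alignment score with linear gap penalty on
// integer-encoded token sequences. Two-row DP; descriptor strings are
// short, the kernel exists so that screening runs over many molecule
// pairs stay fast.
// [[Rcpp::export(name = ".sw_score")]]
int sw_score(Rcpp::IntegerVector a, Rcpp::IntegerVector b,
             int match, int mismatch, int gap) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int s = prev[j - 1] + (a[i - 1] == b[j - 1] ? match : mismatch);
      s = std::max(s, prev[j] + gap);
      s = std::max(s, cur[j - 1] + gap);
      s = std::max(s, 0);
      cur[j] = s;
      if (s > best) best = s;
    }
    std::swap(prev, cur);
  }
  return best;
}
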