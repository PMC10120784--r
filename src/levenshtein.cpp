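#include <Rcpp.h>
using namespace Rcpp;

// Unit-cost Levenshtein distance between two integer-coded token sequences.
// Two-row dynamic programme; tokens are whole syllable types, never the
// characters of a label.
// [[Rcpp::export]]
int lev_dist_int(IntegerVector a, IntegerVector b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      const int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      const int del = prev[j] + 1;
      const int ins = cur[j - 1] + 1;
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
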