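#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Optimal-string-alignment Damerau-Levenshtein distance: substitution,
// insertion, deletion and adjacent transposition, each cost 1; no further
// edit of a transposed substring. Three-row DP.
static int osa_one(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev2(m + 1), prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int d = std::min({prev[j] + 1, cur[j - 1] + 1, prev[j - 1] + cost});
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        d = std::min(d, prev2[j - 2] + 1);
      cur[j] = d;
    }
    std::swap(prev2, prev);
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector osa_distance_cpp(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size())
    stop("a and b must have the same length");
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) {
      out[i] = NA_INTEGER;
    } else {
      out[i] = osa_one(as<std::string>(a[i]), as<std::string>(b[i]));
    }
  }
  return out;
}
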