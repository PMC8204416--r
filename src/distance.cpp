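#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Unit-cost Levenshtein distance between two byte strings.
// Two-row dynamic programme; inputs are cleaned uppercase ASCII so byte
// semantics are safe.
static int lev_one(const std::string &a, const std::string &b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return (int) m;
  if (m == 0) return (int) n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int) j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int) i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      int best = sub < del ? sub : del;
      cur[j] = best < ins ? best : ins;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".lev_pairwise")]]
IntegerVector lev_pairwise(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("a and b must have the same length");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (a[i] == NA_STRING || b[i] == NA_STRING) {
      out[i] = NA_INTEGER;
    } else {
      out[i] = lev_one(std::string(a[i]), std::string(b[i]));
    }
  }
  return out;
}
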