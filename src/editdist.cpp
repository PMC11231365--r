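#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Global (end-to-end) Levenshtein distance, unit costs.
// [[Rcpp::export(name = ".edit_dist_cpp")]]
int edit_dist_cpp(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Semi-global ("infix") Levenshtein: the pattern is aligned end-to-end
// against the best-matching substring of the subject (free gaps at both
// subject ends). Returns c(distance, start, end) with a 1-based, inclusive
// matched span in the subject; ties broken by leftmost end, then by
// shortest span. Empty subject => distance = nchar(pattern), span 0:-1.
// [[Rcpp::export(name = ".infix_edit_cpp")]]
IntegerVector infix_edit_cpp(const std::string& pattern,
                             const std::string& subject) {
  const int n = pattern.size(), m = subject.size();
  // dp over pattern rows; col 0..m, row 0 all zeros (free start in subject)
  std::vector<int> prev(m + 1), cur(m + 1);
  // trace start of match per cell
  std::vector<int> sprev(m + 1), scur(m + 1);
  for (int j = 0; j <= m; ++j) { prev[j] = 0; sprev[j] = j; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i; scur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (pattern[i - 1] == subject[j - 1] ? 0 : 1);
      int del = prev[j] + 1;     // consume pattern char, gap in subject
      int ins = cur[j - 1] + 1;  // consume subject char, gap in pattern
      int best = sub, src = 0;
      if (del < best) { best = del; src = 1; }
      if (ins < best) { best = ins; src = 2; }
      cur[j] = best;
      scur[j] = (src == 0) ? sprev[j - 1] : (src == 1 ? sprev[j] : scur[j - 1]);
    }
    std::swap(prev, cur);
    std::swap(sprev, scur);
  }
  // minimal distance over subject end positions; leftmost end tie-break
  int bestj = 0, bestd = prev[0];
  for (int j = 1; j <= m; ++j)
    if (prev[j] < bestd) { bestd = prev[j]; bestj = j; }
  int start = (bestj == 0) ? 1 : sprev[bestj] + 1; // 1-based
  return IntegerVector::create(bestd, start, bestj);
}

// Vectorised global distance of one string against many.
// [[Rcpp::export(name = ".edit_dist_many_cpp")]]
IntegerVector edit_dist_many_cpp(const std::string& a,
                                 const std::vector<std::string>& bs) {
  IntegerVector out(bs.size());
  for (size_t k = 0; k < bs.size(); ++k) out[k] = edit_dist_cpp(a, bs[k]);
  return out;
}
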