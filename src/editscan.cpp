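#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Semi-global edit distance: best Levenshtein distance of `pattern`
// against any substring of `window` (free start and end in the window).
// Also reports the 1-based end position of the best match, for trimming.
static void semiglobal_edit(const std::string& window, const std::string& pattern,
                            int& best, int& best_end) {
  const int W = (int)window.size(), P = (int)pattern.size();
  std::vector<int> prev(W + 1), cur(W + 1);
  for (int j = 0; j <= W; ++j) prev[j] = 0;  // free start anywhere in window
  for (int i = 1; i <= P; ++i) {
    cur[0] = i;
    for (int j = 1; j <= W; ++j) {
      int sub = prev[j - 1] + (pattern[i - 1] == window[j - 1] ? 0 : 1);
      int del = prev[j] + 1;   // skip pattern base
      int ins = cur[j - 1] + 1; // extra window base
      cur[j] = std::min(sub, std::min(del, ins));
    }
    std::swap(prev, cur);
  }
  best = P; best_end = 0;
  for (int j = 1; j <= W; ++j) {
    if (prev[j] < best) { best = prev[j]; best_end = j; }
  }
}

// [[Rcpp::export]]
List edit_scan_cpp(CharacterVector windows, CharacterVector patterns) {
  const int n = windows.size(), m = patterns.size();
  IntegerMatrix dist(n, m), endpos(n, m);
  std::vector<std::string> pats(m);
  for (int k = 0; k < m; ++k) pats[k] = as<std::string>(patterns[k]);
  for (int i = 0; i < n; ++i) {
    std::string w = as<std::string>(windows[i]);
    for (int k = 0; k < m; ++k) {
      int b, e;
      semiglobal_edit(w, pats[k], b, e);
      dist(i, k) = b; endpos(i, k) = e;
    }
  }
  return List::create(_["dist"] = dist, _["end"] = endpos);
}
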