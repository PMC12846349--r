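#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Longest border (proper prefix equal to suffix) of s no longer than maxk,
// via the Knuth-Morris-Pratt failure function. Used for direct terminal
// repeat detection on ~100 kb genomes.
// [[Rcpp::export]]
int kmp_border_cpp(std::string s, int maxk = -1) {
  const int n = (int) s.size();
  if (n == 0) return 0;
  std::vector<int> pi(n, 0);
  for (int i = 1; i < n; ++i) {
    int k = pi[i - 1];
    while (k > 0 && s[i] != s[k]) k = pi[k - 1];
    if (s[i] == s[k]) ++k;
    pi[i] = k;
  }
  int k = pi[n - 1];
  if (maxk < 0) maxk = n;
  // borders form a chain k, pi[k-1], ...; take the longest one <= maxk
  while (k > maxk) k = pi[k - 1];
  return k;
}

// Needleman-Wunsch global alignment with linear gap penalty and
// deterministic traceback (prefer diagonal, then up = gap in b,
// then left = gap in a).
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = (int) a.size(), m = (int) b.size();
  std::vector<double> dp((n + 1) * (m + 1));
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int i = 0; i <= n; ++i) dp[at(i, 0)] = gap * i;
  for (int j = 0; j <= m; ++j) dp[at(0, j)] = gap * j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sub = dp[at(i - 1, j - 1)] +
        (a[i - 1] == b[j - 1] ? match : mismatch);
      double up = dp[at(i - 1, j)] + gap;
      double left = dp[at(i, j - 1)] + gap;
      double best = sub;
      if (up > best) best = up;
      if (left > best) best = left;
      dp[at(i, j)] = best;
    }
  }
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        dp[at(i, j)] == dp[at(i - 1, j - 1)] +
          (a[i - 1] == b[j - 1] ? match : mismatch)) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && dp[at(i, j)] == dp[at(i - 1, j)] + gap) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb,
                      _["score"] = dp[at(n, m)]);
}
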