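// Ends-free (overlap / dovetail / containment) pairwise alignment with unit
// scores: match +1, mismatch -1, linear gap -1; N never matches. Leading and
// trailing gaps of either sequence are free. Ties in the traceback prefer
// diagonal, then a gap in the subject, then a gap in the pattern, which makes
// the reported alignment deterministic.

#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// [[Rcpp::export(name = ".ov_align_cpp")]]
List ov_align_cpp(std::string a, std::string b) {
  const int m = a.size(), n = b.size();
  std::vector<int> H((m + 1) * (n + 1));
  const int W = n + 1;
  for (int j = 0; j <= n; ++j) H[j] = 0;
  for (int i = 0; i <= m; ++i) H[i * W] = 0;
  for (int i = 1; i <= m; ++i) {
    const char ai = a[i - 1];
    int* row = &H[i * W];
    const int* prev = &H[(i - 1) * W];
    for (int j = 1; j <= n; ++j) {
      const char bj = b[j - 1];
      const int s = (ai == bj && ai != 'N') ? 1 : -1;
      int best = prev[j - 1] + s;
      const int up = prev[j] - 1;
      if (up > best) best = up;
      const int left = row[j - 1] - 1;
      if (left > best) best = left;
      row[j] = best;
    }
  }
  // best end on the last row or last column (free trailing overhangs)
  int bi = m, bj = n, bscore = H[m * W + n];
  for (int j = 0; j <= n; ++j) {
    if (H[m * W + j] > bscore) { bscore = H[m * W + j]; bi = m; bj = j; }
  }
  for (int i = 0; i <= m; ++i) {
    if (H[i * W + n] > bscore) { bscore = H[i * W + n]; bi = i; bj = n; }
  }
  // traceback to the top or left boundary
  std::string aa, bb;
  int i = bi, j = bj, matches = 0;
  while (i > 0 && j > 0) {
    const int cur = H[i * W + j];
    const char ai = a[i - 1], bj_ = b[j - 1];
    const int s = (ai == bj_ && ai != 'N') ? 1 : -1;
    if (cur == H[(i - 1) * W + (j - 1)] + s) {
      aa.push_back(ai); bb.push_back(bj_);
      if (s == 1) ++matches;
      --i; --j;
    } else if (cur == H[(i - 1) * W + j] - 1) {
      aa.push_back(ai); bb.push_back('-');
      --i;
    } else {
      aa.push_back('-'); bb.push_back(bj_);
      --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  const int cols = aa.size();
  return List::create(
    _["score"] = bscore,
    _["columns"] = cols,
    _["matches"] = matches,
    _["p_start"] = i + 1, _["p_end"] = bi,
    _["s_start"] = j + 1, _["s_end"] = bj,
    _["ap"] = aa, _["as"] = bb);
}
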