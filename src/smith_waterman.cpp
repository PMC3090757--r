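#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps.
// q, t: 1-based indices into the substitution matrix S.
// Gap of length k costs gap_open + k * gap_extend.
// All scores are whole numbers, so double comparisons in the
// traceback are exact.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector t, NumericMatrix S,
                  double gap_open, double gap_extend) {
  const int n = q.size(), m = t.size();
  const double NEG = -1e30;
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int qi = q[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      // E: gap in query (consumes target residue j)
      double e = std::max(H(i, j - 1) - gap_open - gap_extend,
                          E(i, j - 1) - gap_extend);
      // F: gap in target (consumes query residue i)
      double f = std::max(H(i - 1, j) - gap_open - gap_extend,
                          F(i - 1, j) - gap_extend);
      double h = H(i - 1, j - 1) + S(qi, t[j - 1] - 1);
      double v = std::max(0.0, std::max(h, std::max(e, f)));
      E(i, j) = e;
      F(i, j) = f;
      H(i, j) = v;
      if (v > best) { best = v; bi = i; bj = j; }  // strict >: earliest end
    }
  }

  std::vector<int> qa, ta;
  if (best > 0.0) {
    int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
    while (i > 0 && j > 0) {
      if (state == 0) {
        if (H(i, j) == 0.0) break;
        double h = H(i - 1, j - 1) + S(q[i - 1] - 1, t[j - 1] - 1);
        if (H(i, j) == h) {
          qa.push_back(i); ta.push_back(j); --i; --j;
        } else if (H(i, j) == E(i, j)) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {
        qa.push_back(NA_INTEGER); ta.push_back(j);
        if (E(i, j) == H(i, j - 1) - gap_open - gap_extend) state = 0;
        --j;
      } else {
        qa.push_back(i); ta.push_back(NA_INTEGER);
        if (F(i, j) == H(i - 1, j) - gap_open - gap_extend) state = 0;
        --i;
      }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(ta.begin(), ta.end());
  }
  return List::create(_["score"] = best,
                      _["q"] = wrap(qa),
                      _["t"] = wrap(ta));
}
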