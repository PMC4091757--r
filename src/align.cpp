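#include <Rcpp.h>
using namespace Rcpp;

// Gotoh global alignment over a precomputed column-score matrix.
// S(i-1, j-1) is the score of pairing position i of A with position j of B,
// so the same routine serves sequence-sequence (match/mismatch or a
// substitution table) and profile-profile (sum-of-pairs expected score)
// alignment. A gap run of length k costs gapOpen + (k-1) * gapExtend,
// gapOpen <= gapExtend <= 0. Traceback ties prefer diagonal, then up
// (gap in B), then left (gap in A), making the alignment deterministic.
//
// Returns 1-based column indices ai/bi with 0 marking a gap, plus the score.

// [[Rcpp::export]]
List gotoh_align(NumericMatrix S, double gapOpen, double gapExtend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;

  // state 0 = M (diagonal), 1 = X (up, consumes A), 2 = Y (left, consumes B)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix pm(n + 1, m + 1), px(n + 1, m + 1), py(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = gapOpen + (i - 1) * gapExtend;
    px(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = gapOpen + (j - 1) * gapExtend;
    py(0, j) = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double bm = M(i - 1, j - 1); int sm = 0;
      if (X(i - 1, j - 1) > bm) { bm = X(i - 1, j - 1); sm = 1; }
      if (Y(i - 1, j - 1) > bm) { bm = Y(i - 1, j - 1); sm = 2; }
      M(i, j) = bm + S(i - 1, j - 1); pm(i, j) = sm;

      double xm = M(i - 1, j) + gapOpen; int sx = 0;
      if (X(i - 1, j) + gapExtend > xm) { xm = X(i - 1, j) + gapExtend; sx = 1; }
      if (Y(i - 1, j) + gapOpen   > xm) { xm = Y(i - 1, j) + gapOpen;   sx = 2; }
      X(i, j) = xm; px(i, j) = sx;

      double ym = M(i, j - 1) + gapOpen; int sy = 0;
      if (X(i, j - 1) + gapOpen   > ym) { ym = X(i, j - 1) + gapOpen;   sy = 1; }
      if (Y(i, j - 1) + gapExtend > ym) { ym = Y(i, j - 1) + gapExtend; sy = 2; }
      Y(i, j) = ym; py(i, j) = sy;
    }
  }

  double best = M(n, m); int st = 0;
  if (X(n, m) > best) { best = X(n, m); st = 1; }
  if (Y(n, m) > best) { best = Y(n, m); st = 2; }

  std::vector<int> ai, bi;
  ai.reserve(n + m); bi.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == 0)      { ai.push_back(i); bi.push_back(j); st = pm(i, j); --i; --j; }
    else if (st == 1) { ai.push_back(i); bi.push_back(0); st = px(i, j); --i; }
    else              { ai.push_back(0); bi.push_back(j); st = py(i, j); --j; }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["ai"] = wrap(ai), _["bi"] = wrap(bi),
                      _["score"] = best);
}
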