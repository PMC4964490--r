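#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Needleman-Wunsch (Gotoh) over a precomputed column-pair
// score matrix (profile-profile alignment). End gaps are charged.
// Returns the aligned column indices of the two profiles, 0 denoting a
// gap column. Tie-break order at equal score: match state, then gap in
// the second profile, then gap in the first, which keeps the traceback
// deterministic.
// [[Rcpp::export(name = ".profile_align_path")]]
List profile_align_path(NumericMatrix S, double gap_open, double gap_ext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e18;
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);  // gap run in cols of B
  std::vector<double> Y((n + 1) * (m + 1), NEG);  // gap run in cols of A
  std::vector<signed char> tM((n + 1) * (m + 1), -1);
  std::vector<signed char> tX((n + 1) * (m + 1), -1);
  std::vector<signed char> tY((n + 1) * (m + 1), -1);
  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = -(gap_open + i * gap_ext);
    tX[idx(i, 0)] = (i == 1) ? 0 : 1;   // 0 = from M, 1 = extend X
  }
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = -(gap_open + j * gap_ext);
    tY[idx(0, j)] = (j == 1) ? 0 : 2;   // 2 = extend Y
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = S(i - 1, j - 1);
      // M: consume one column of each
      double bm = M[idx(i - 1, j - 1)]; signed char tb = 0;
      if (X[idx(i - 1, j - 1)] > bm) { bm = X[idx(i - 1, j - 1)]; tb = 1; }
      if (Y[idx(i - 1, j - 1)] > bm) { bm = Y[idx(i - 1, j - 1)]; tb = 2; }
      M[idx(i, j)] = bm + s; tM[idx(i, j)] = tb;
      // X: consume a column of A against a gap
      double open = M[idx(i - 1, j)] - gap_open - gap_ext;
      double ext = X[idx(i - 1, j)] - gap_ext;
      if (open >= ext) { X[idx(i, j)] = open; tX[idx(i, j)] = 0; }
      else { X[idx(i, j)] = ext; tX[idx(i, j)] = 1; }
      // Y: consume a column of B against a gap
      open = M[idx(i, j - 1)] - gap_open - gap_ext;
      ext = Y[idx(i, j - 1)] - gap_ext;
      if (open >= ext) { Y[idx(i, j)] = open; tY[idx(i, j)] = 0; }
      else { Y[idx(i, j)] = ext; tY[idx(i, j)] = 2; }
    }
  }
  double best = M[idx(n, m)]; int state = 0;
  if (X[idx(n, m)] > best) { best = X[idx(n, m)]; state = 1; }
  if (Y[idx(n, m)] > best) { best = Y[idx(n, m)]; state = 2; }
  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char tb = tM[idx(i, j)];
      ai.push_back(i); bi.push_back(j); --i; --j; state = tb;
    } else if (state == 1) {
      signed char tb = tX[idx(i, j)];
      ai.push_back(i); bi.push_back(0); --i; state = (tb == 1) ? 1 : 0;
    } else {
      signed char tb = tY[idx(i, j)];
      ai.push_back(0); bi.push_back(j); --j; state = (tb == 2) ? 2 : 0;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = best);
}
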