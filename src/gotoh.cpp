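#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh three-state DP).
// Penalties are positive magnitudes; a gap run of length k costs
// open + k * ext (the first gapped position pays both). The alternative
// convention (open inclusive of the first extend) is handled in R by
// shifting open. States: M (match), X (gap in b, consumes a), Y (gap in a,
// consumes b). Tie-break order everywhere: M, then X, then Y.
//
// [[Rcpp::export]]
List gotoh_align(IntegerVector a, IntegerVector b, NumericMatrix s,
                 double open, double ext, bool free_ends) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double go = open + ext;  // cost of opening (first gapped position)

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix pM(n + 1, m + 1), pX(n + 1, m + 1), pY(n + 1, m + 1);
  // predecessor codes: 0 = M, 1 = X, 2 = Y

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = free_ends ? 0.0 : -(open + i * ext);
    pX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = free_ends ? 0.0 : -(open + j * ext);
    pY(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // match state
      double best = M(i - 1, j - 1); int arg = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); arg = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); arg = 2; }
      M(i, j) = best + s(a[i - 1] - 1, b[j - 1] - 1);
      pM(i, j) = arg;
      // gap in b (consume a)
      best = M(i - 1, j) - go; arg = 0;
      if (X(i - 1, j) - ext > best) { best = X(i - 1, j) - ext; arg = 1; }
      if (Y(i - 1, j) - go > best) { best = Y(i - 1, j) - go; arg = 2; }
      X(i, j) = best; pX(i, j) = arg;
      // gap in a (consume b)
      best = M(i, j - 1) - go; arg = 0;
      if (X(i, j - 1) - go > best) { best = X(i, j - 1) - go; arg = 1; }
      if (Y(i, j - 1) - ext > best) { best = Y(i, j - 1) - ext; arg = 2; }
      Y(i, j) = best; pY(i, j) = arg;
    }
  }

  // terminal cell and state (free_ends: best over last row/column with the
  // trailing gap uncharged)
  int ei = n, ej = m, state = 0;
  double score;
  {
    double bM = M(n, m), bX = X(n, m), bY = Y(n, m);
    score = bM; state = 0;
    if (bX > score) { score = bX; state = 1; }
    if (bY > score) { score = bY; state = 2; }
  }
  if (free_ends && n > 0 && m > 0) {
    for (int i = 0; i <= n; ++i) {
      for (int st = 0; st < 3; ++st) {
        double v = (st == 0 ? M(i, m) : st == 1 ? X(i, m) : Y(i, m));
        if (v > score) { score = v; ei = i; ej = m; state = st; }
      }
    }
    for (int j = 0; j <= m; ++j) {
      for (int st = 0; st < 3; ++st) {
        double v = (st == 0 ? M(n, j) : st == 1 ? X(n, j) : Y(n, j));
        if (v > score) { score = v; ei = n; ej = j; state = st; }
      }
    }
  }

  // traceback (free trailing gaps appended first)
  std::vector<int> ai, bi;
  for (int i = n; i > ei; --i) { ai.push_back(i); bi.push_back(0); }
  for (int j = m; j > ej; --j) { ai.push_back(0); bi.push_back(j); }
  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = pM(i, j);
      ai.push_back(i); bi.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = pX(i, j);
      ai.push_back(i); bi.push_back(0);
      --i; state = prev;
    } else {
      int prev = pY(i, j);
      ai.push_back(0); bi.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi.begin(), bi.end()));
}
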