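#include <Rcpp.h>
using namespace Rcpp;

// Global alignment of two profiles (or sequences) with affine gaps (Gotoh).
// S is the precomputed column-vs-column score matrix (L1 x L2).  Returns the
// aligned index vectors (1-based positions, 0 = gap) and the optimal score.
// [[Rcpp::export]]
List cpp_affine_align(NumericMatrix S, double gap_open, double gap_ext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  // M: ends in match; E: ends in gap in seq1 (horizontal); F: gap in seq2.
  NumericMatrix M(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbE(n + 1, m + 1), tbF(n + 1, m + 1);
  M(0, 0) = 0.0; E(0, 0) = NEG; F(0, 0) = NEG;
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; F(0, j) = NEG;
    E(0, j) = -gap_open - gap_ext * (j - 1);
    tbE(0, j) = 1; // came from E
  }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; E(i, 0) = NEG;
    F(i, 0) = -gap_open - gap_ext * (i - 1);
    tbF(i, 0) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M
      double best = M(i - 1, j - 1); int tb = 0;
      if (E(i - 1, j - 1) > best) { best = E(i - 1, j - 1); tb = 1; }
      if (F(i - 1, j - 1) > best) { best = F(i - 1, j - 1); tb = 2; }
      M(i, j) = best + S(i - 1, j - 1); tbM(i, j) = tb;
      // E: gap in seq1, consume column j of seq2
      double eo = M(i, j - 1) - gap_open;
      double ee = E(i, j - 1) - gap_ext;
      double ef = F(i, j - 1) - gap_open;
      if (eo >= ee && eo >= ef) { E(i, j) = eo; tbE(i, j) = 0; }
      else if (ee >= ef)        { E(i, j) = ee; tbE(i, j) = 1; }
      else                      { E(i, j) = ef; tbE(i, j) = 2; }
      // F: gap in seq2, consume row i of seq1
      double fo = M(i - 1, j) - gap_open;
      double fe = F(i - 1, j) - gap_ext;
      double fE = E(i - 1, j) - gap_open;
      if (fo >= fe && fo >= fE) { F(i, j) = fo; tbF(i, j) = 0; }
      else if (fe >= fE)        { F(i, j) = fe; tbF(i, j) = 1; }
      else                      { F(i, j) = fE; tbF(i, j) = 2; }
    }
  }
  // traceback
  int state; double score;
  if (M(n, m) >= E(n, m) && M(n, m) >= F(n, m)) { state = 0; score = M(n, m); }
  else if (E(n, m) >= F(n, m))                  { state = 1; score = E(n, m); }
  else                                          { state = 2; score = F(n, m); }
  std::vector<int> a1, a2;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM(i, j);
      a1.push_back(i); a2.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbE(i, j);
      a1.push_back(0); a2.push_back(j);
      --j; state = prev;
    } else {
      int prev = tbF(i, j);
      a1.push_back(i); a2.push_back(0);
      --i; state = prev;
    }
  }
  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());
  return List::create(_["idx1"] = wrap(a1), _["idx2"] = wrap(a2),
                      _["score"] = score);
}

// Weighted pairwise mismatch distances over the columns of an integer-coded
// alignment (rows = sequences).  Columns where both sequences carry gap_code
// are skipped; w gives per-column weights (bootstrap resampling counts).
// dist = sum w * mismatch / sum w over comparable columns; NaN when none.
// [[Rcpp::export]]
NumericMatrix cpp_mismatch_dist(IntegerMatrix M, NumericVector w, int gap_code) {
  const int n = M.nrow(), L = M.ncol();
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double mis = 0.0, tot = 0.0;
      for (int k = 0; k < L; ++k) {
        const int a = M(i, k), b = M(j, k);
        if (a == gap_code && b == gap_code) continue;
        const double wk = w[k];
        tot += wk;
        if (a != b) mis += wk;
      }
      const double d = tot > 0.0 ? mis / tot : NA_REAL;
      D(i, j) = d; D(j, i) = d;
    }
  }
  return D;
}

// Identity between two integer-coded unaligned-but-positionally-comparable
// vectors (equal length), i.e. a Hamming identity.
// [[Rcpp::export]]
double cpp_hamming_identity(IntegerVector a, IntegerVector b) {
  const int L = a.size();
  if (L != b.size() || L == 0) return NA_REAL;
  int match = 0;
  for (int k = 0; k < L; ++k) if (a[k] == b[k]) ++match;
  return (double)match / (double)L;
}
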