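#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment of two sequence profiles with
// affine gap costs. Profiles are integer matrices (rows = sequences,
// cols = positions) with codes 0=A,1=C,2=G,3=T,4=N,5=gap. Column-column
// substitution score is the average pairwise score over non-gap residue
// pairs; N scores as mismatch against everything, including N. A gap of
// length k costs gap_open + (k-1)*gap_extend (the opening cost covers the
// first gapped column). Traceback tie-break: diagonal > up (gap in B) >
// left (gap in A), giving a deterministic alignment.

static inline double col_score(const IntegerMatrix& A, int ca,
                               const IntegerMatrix& B, int cb,
                               double match, double mismatch) {
  double s = 0.0;
  int n = 0;
  for (int i = 0; i < A.nrow(); ++i) {
    int a = A(i, ca);
    if (a == 5) continue;
    for (int j = 0; j < B.nrow(); ++j) {
      int b = B(j, cb);
      if (b == 5) continue;
      s += (a == b && a < 4) ? match : mismatch;
      ++n;
    }
  }
  return n ? s / n : 0.0;
}

// [[Rcpp::export(name = ".align_profiles_cpp")]]
List align_profiles_cpp(IntegerMatrix A, IntegerMatrix B,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
  const int n = A.ncol(), m = B.ncol();
  const double NEG = -1e30;
  // DP matrices: M (diag), X (gap in B: consume A col), Y (gap in A)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i,j) = NEG; X(i,j) = NEG; Y(i,j) = NEG; }
  M(0,0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i,0) = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y(0,j) = gap_open + (j - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sc = col_score(A, i - 1, B, j - 1, match, mismatch);
      double best = M(i-1,j-1);
      if (X(i-1,j-1) > best) best = X(i-1,j-1);
      if (Y(i-1,j-1) > best) best = Y(i-1,j-1);
      if (best > NEG / 2) M(i,j) = best + sc;
      double xo = M(i-1,j) + gap_open;
      double xe = X(i-1,j) + gap_extend;
      double xy = Y(i-1,j) + gap_open;
      X(i,j) = std::max(xo, std::max(xe, xy));
      double yo = M(i,j-1) + gap_open;
      double ye = Y(i,j-1) + gap_extend;
      double yx = X(i,j-1) + gap_open;
      Y(i,j) = std::max(yo, std::max(ye, yx));
    }
  }
  double score = M(n,m);
  int state = 0;                      // 0=M, 1=X, 2=Y; preference M > X > Y
  if (X(n,m) > score) { score = X(n,m); state = 1; }
  if (Y(n,m) > score) { score = Y(n,m); state = 2; }

  std::vector<int> ia, ib;            // 1-based source columns, 0 = gap
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      ia.push_back(i); ib.push_back(j);
      double sc = col_score(A, i - 1, B, j - 1, match, mismatch);
      double prev = M(i,j) - sc;
      // preference diag(M) > up(X) > left(Y)
      if (std::abs(M(i-1,j-1) - prev) < 1e-9) state = 0;
      else if (std::abs(X(i-1,j-1) - prev) < 1e-9) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {          // consume A column, gap in B
      ia.push_back(i); ib.push_back(0);
      double cur = X(i,j);
      if (std::abs(M(i-1,j) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(X(i-1,j) + gap_extend - cur) < 1e-9) state = 1;
      else state = 2;
      --i;
    } else {                          // consume B column, gap in A
      ia.push_back(0); ib.push_back(j);
      double cur = Y(i,j);
      if (std::abs(M(i,j-1) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(Y(i,j-1) + gap_extend - cur) < 1e-9) state = 2;
      else state = 1;
      --j;
    }
  }
  std::reverse(ia.begin(), ia.end());
  std::reverse(ib.begin(), ib.end());
  return List::create(_["score"] = score,
                      _["a_cols"] = wrap(ia),
                      _["b_cols"] = wrap(ib));
}
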