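#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Local alignment kernel (sum over all local alignments of exp(beta * score))
// with affine gaps: a gap of length g costs gap_open + g * gap_extend.
// Returns log K(x, y); computed in log-sum-exp-free double space with a
// running scale factor to avoid overflow on long sequences.
//
// x, y: 1-based residue codes into the substitution matrix.
// [[Rcpp::export(name = ".lak_logk")]]
double lak_logk(IntegerVector x, IntegerVector y, NumericMatrix submat,
                double beta, double gap_open, double gap_extend) {
  int n = x.size(), m = y.size();
  double eo = std::exp(-beta * (gap_open + gap_extend));
  double ee = std::exp(-beta * gap_extend);

  std::vector<double> M(m + 1, 0.0), X(m + 1, 0.0), Y(m + 1, 0.0),
      X2(m + 1, 0.0), Y2(m + 1, 0.0);
  std::vector<double> Mp(m + 1, 0.0), Xp(m + 1, 0.0), Yp(m + 1, 0.0),
      X2p(m + 1, 0.0), Y2p(m + 1, 0.0);

  double logscale = 0.0;
  double one = 1.0;  // the empty-alignment unit, kept on the current scale
  const double big = 1e250;

  for (int i = 1; i <= n; ++i) {
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
    std::swap(X2, X2p); std::swap(Y2, Y2p);
    M[0] = X[0] = Y[0] = X2[0] = Y2[0] = 0.0;
    double rowmax = 0.0;
    for (int j = 1; j <= m; ++j) {
      double s = std::exp(beta * submat(x[i - 1] - 1, y[j - 1] - 1));
      M[j] = s * (one + Xp[j - 1] + Yp[j - 1] + Mp[j - 1]);
      X[j] = eo * Mp[j] + ee * Xp[j];
      Y[j] = eo * (M[j - 1] + X[j - 1]) + ee * Y[j - 1];
      X2[j] = Mp[j] + X2p[j];
      Y2[j] = M[j - 1] + X2[j - 1] + Y2[j - 1];
      double mx = std::max({M[j], X[j], Y[j], X2[j], Y2[j]});
      if (mx > rowmax) rowmax = mx;
    }
    if (rowmax > big) {
      double f = 1.0 / rowmax;
      logscale += std::log(rowmax);
      one *= f;
      for (int j = 0; j <= m; ++j) {
        M[j] *= f; X[j] *= f; Y[j] *= f; X2[j] *= f; Y2[j] *= f;
        Mp[j] *= f; Xp[j] *= f; Yp[j] *= f; X2p[j] *= f; Y2p[j] *= f;
      }
    }
  }
  double k = one + X2[m] + Y2[m] + M[m];
  return std::log(k) + logscale;
}
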