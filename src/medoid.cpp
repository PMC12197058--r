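#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Cumulative sign-ambiguous distances for the medoid search.
//
// For quaternions a, b (rows of X, one quaternion per row, 4 columns) the
// distance is d(a,b) = min(||a-b||, ||a+b||).  Writing s_i = ||q_i||^2 and
// G_ij = <q_i, q_j>, one has ||q_i -+ q_j||^2 = s_i + s_j -+ 2 G_ij, so
// d(q_i,q_j)^2 = s_i + s_j - 2|G_ij|.  The full n x n sweep is quadratic in
// the sequence length (n = 3000 for a one-minute recording at 50 Hz), hence
// compiled.

// [[Rcpp::export]]
NumericVector medoid_objectives_cpp(NumericMatrix X) {
  const int n = X.nrow();
  if (X.ncol() != 4) stop("expected a matrix with 4 columns");
  std::vector<double> sq(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int c = 0; c < 4; ++c) s += X(i, c) * X(i, c);
    sq[i] = s;
  }
  NumericVector obj(n);
  for (int i = 0; i < n; ++i) {
    const double xi0 = X(i, 0), xi1 = X(i, 1), xi2 = X(i, 2), xi3 = X(i, 3);
    for (int j = i + 1; j < n; ++j) {
      double dot = xi0 * X(j, 0) + xi1 * X(j, 1) + xi2 * X(j, 2) + xi3 * X(j, 3);
      double d2 = sq[i] + sq[j] - 2.0 * std::fabs(dot);
      double d = d2 > 0.0 ? std::sqrt(d2) : 0.0;  // guard fp cancellation
      obj[i] += d;
      obj[j] += d;
    }
  }
  return obj;
}
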