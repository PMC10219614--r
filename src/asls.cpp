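#include <Rcpp.h>
using namespace Rcpp;

// Asymmetric least squares baseline (Eilers-type): minimise
//   sum_i w_i (y_i - z_i)^2 + lambda * sum (delta^2 z)^2
// with asymmetric weights w_i = p if y_i > z_i else 1 - p, iterated a
// fixed number of times. The normal-matrix W + lambda * D'D is
// pentadiagonal, so each iterate is an O(n) banded LDL' solve.

// [[Rcpp::export]]
List asls_baseline_cpp(NumericVector y, double lambda, double p, int maxit) {
  const int n = y.size();
  if (n < 5) stop("AsLS requires at least 5 points");

  // D'D bands for the second-difference penalty
  std::vector<double> p0(n), p1(n - 1, -4.0), p2(n - 2, 1.0);
  for (int i = 0; i < n; ++i) p0[i] = 6.0;
  p0[0] = p0[n - 1] = 1.0;
  p0[1] = p0[n - 2] = 5.0;
  p1[0] = p1[n - 2] = -2.0;

  std::vector<double> w(n, 1.0), wprev(n), z(n, 0.0);
  std::vector<double> Dg(n), m1(n), m2(n), s(n);
  bool converged = false;
  int iter = 0;

  for (iter = 0; iter < maxit; ++iter) {
    // factorise A = diag(w) + lambda * D'D  (banded LDL')
    for (int i = 0; i < n; ++i) {
      double e2 = (i >= 2) ? lambda * p2[i - 2] : 0.0;
      double e1 = (i >= 1) ? lambda * p1[i - 1] : 0.0;
      double l2 = (i >= 2) ? e2 / Dg[i - 2] : 0.0;
      double l1 = (i >= 1)
        ? (e1 - ((i >= 2) ? l2 * Dg[i - 2] * m1[i - 1] : 0.0)) / Dg[i - 1]
        : 0.0;
      m2[i] = l2;
      m1[i] = l1;
      double d = w[i] + lambda * p0[i];
      if (i >= 2) d -= l2 * l2 * Dg[i - 2];
      if (i >= 1) d -= l1 * l1 * Dg[i - 1];
      Dg[i] = d;
    }
    // solve A z = w * y
    for (int i = 0; i < n; ++i) {
      double v = w[i] * y[i];
      if (i >= 1) v -= m1[i] * s[i - 1];
      if (i >= 2) v -= m2[i] * s[i - 2];
      s[i] = v;
    }
    for (int i = 0; i < n; ++i) s[i] /= Dg[i];
    for (int i = n - 1; i >= 0; --i) {
      double v = s[i];
      if (i + 1 < n) v -= m1[i + 1] * z[i + 1];
      if (i + 2 < n) v -= m2[i + 2] * z[i + 2];
      z[i] = v;
    }
    // asymmetric reweighting
    wprev = w;
    for (int i = 0; i < n; ++i) w[i] = (y[i] > z[i]) ? p : 1.0 - p;
    bool same = true;
    for (int i = 0; i < n; ++i)
      if (w[i] != wprev[i]) { same = false; break; }
    if (same) { converged = true; break; }
  }

  return List::create(
    _["baseline"] = NumericVector(z.begin(), z.end()),
    _["converged"] = converged,
    _["iterations"] = iter + 1
  );
}
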