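#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Direct form II transposed IIR filter with explicit initial state.
// b, a: numerator/denominator coefficients; zi: initial conditions of the
// filter delays (length max(length(a), length(b)) - 1, zero-padded if short).
// [[Rcpp::export]]
NumericVector iir_filter_core(NumericVector b, NumericVector a,
                              NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nf = std::max(na, nb);
  if (nf < 2) stop("filter must have order >= 1");
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  double a0 = aa[0];
  if (a0 == 0.0) stop("a[1] must be nonzero");
  for (int i = 0; i < nf; ++i) { bb[i] /= a0; aa[i] /= a0; }
  std::vector<double> z(nf - 1, 0.0);
  int nzi = zi.size();
  for (int i = 0; i < nf - 1 && i < nzi; ++i) z[i] = zi[i];

  int n = x.size();
  NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    double xt = x[t];
    double yt = bb[0] * xt + z[0];
    for (int k = 0; k < nf - 2; ++k)
      z[k] = bb[k + 1] * xt + z[k + 1] - aa[k + 1] * yt;
    z[nf - 2] = bb[nf - 1] * xt - aa[nf - 1] * yt;
    y[t] = yt;
  }
  return y;
}

// Forward pass of the physiological torque model at full sample rate.
// env: N x M matrix of muscle envelopes in [0,1] (columns = channels);
// idx: 1-based, strictly increasing sample indices at which torque is
// evaluated (decimation happens here, after the recursion);
// d_samp: electromechanical delay in whole samples; alpha, b1, b2:
// activation-dynamics coefficients (alpha = 1 + b1 + b2 ensures unit DC
// gain); A: nonlinear shape factor in [-3, 0]; w: per-channel torque weight
// (SigmaPCSA/PCSA * Fmax * MA), N*m per unit activation.
// [[Rcpp::export]]
NumericVector pbm_forward_core(NumericMatrix env, IntegerVector idx,
                               int d_samp, double alpha, double b1, double b2,
                               double A, NumericVector w) {
  int n = env.nrow(), m = env.ncol();
  int nout = idx.size();
  if (w.size() != m) stop("one weight per channel required");
  for (int i = 0; i < nout; ++i) {
    if (idx[i] < 1 || idx[i] > n) stop("idx out of range");
    if (i > 0 && idx[i] <= idx[i - 1]) stop("idx must be strictly increasing");
  }
  NumericVector tau(nout);
  bool linear = (A > -1e-12);
  double denom = linear ? 1.0 : std::expm1(A);
  for (int j = 0; j < m; ++j) {
    double u1 = 0.0, u2 = 0.0, wj = w[j];
    int p = 0;
    for (int t = 0; t < n && p < nout; ++t) {
      double e = (t >= d_samp) ? env(t - d_samp, j) : 0.0;
      double u = alpha * e - b1 * u1 - b2 * u2;
      u2 = u1;
      u1 = u;
      if (idx[p] == t + 1) {
        double uc = u < 0.0 ? 0.0 : (u > 1.0 ? 1.0 : u);
        double a = linear ? uc : std::expm1(A * uc) / denom;
        tau[p] += wj * a;
        ++p;
      }
    }
  }
  return tau;
}
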