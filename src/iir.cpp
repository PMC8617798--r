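#include <Rcpp.h>
using namespace Rcpp;

// One IIR pass over n samples with zero initial conditions; x and y may
// not alias. a[0] is assumed 1. step = +1 walks forward, -1 backward.
static void iir_pass(const double* b, int nb, const double* a, int na,
                     const double* x, double* y, int n, int step) {
  const int start = step > 0 ? 0 : n - 1;
  for (int k = 0; k < n; ++k) {
    const int t = start + step * k;
    double acc = 0.0;
    const int ib = std::min(nb - 1, k);
    for (int i = 0; i <= ib; ++i) acc += b[i] * x[t - step * i];
    const int ia = std::min(na - 1, k);
    for (int i = 1; i <= ia; ++i) acc -= a[i] * y[t - step * i];
    y[t] = acc;
  }
}

// [[Rcpp::export(name = ".iir_filtfilt_cpp")]]
NumericMatrix iir_filtfilt_cpp(NumericVector b, NumericVector a,
                               NumericMatrix X) {
  if (a.size() < 1 || a[0] != 1.0) stop("a[0] must be 1");
  const int n = X.nrow(), m = X.ncol();
  const int nb = b.size(), na = a.size();
  NumericMatrix Y(n, m);
  std::vector<double> tmp(n);
  for (int c = 0; c < m; ++c) {
    const double* xc = &X[0] + (size_t)c * n;
    double* yc = &Y[0] + (size_t)c * n;
    iir_pass(b.begin(), nb, a.begin(), na, xc, tmp.data(), n, +1);
    iir_pass(b.begin(), nb, a.begin(), na, tmp.data(), yc, n, -1);
  }
  return Y;
}
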