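#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filtering of every column of X (a[0] must
// be 1). `zi` is the unit-step steady-state of the filter state; per
// column it is scaled by the first sample so that a constant input passes
// through without transient. The recursive pass is inherently sequential
// in t, which is why this lives in C++.
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericMatrix iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericMatrix X, NumericVector zi) {
  const int n = X.nrow(), V = X.ncol();
  const int nb = b.size(), na = a.size();
  const int ns = (nb > na ? nb : na) - 1;  // state length
  const double *bp = b.begin(), *ap = a.begin(), *zp = zi.begin();
  std::vector<double> bb(ns + 1, 0.0), aa(ns + 1, 0.0), z(ns, 0.0);
  for (int j = 0; j < nb; ++j) bb[j] = bp[j];
  for (int j = 0; j < na; ++j) aa[j] = ap[j];
  NumericMatrix Y(n, V);
  for (int v = 0; v < V; ++v) {
    const double *x = &X(0, v);
    double *y = &Y(0, v);
    const double scale = x[0];
    for (int j = 0; j < ns; ++j) z[j] = zp[j] * scale;
    for (int t = 0; t < n; ++t) {
      const double xt = x[t];
      const double yt = bb[0] * xt + z[0];
      for (int j = 0; j < ns - 1; ++j)
        z[j] = bb[j + 1] * xt + z[j + 1] - aa[j + 1] * yt;
      z[ns - 1] = bb[ns] * xt - aa[ns] * yt;
      y[t] = yt;
    }
  }
  return Y;
}
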