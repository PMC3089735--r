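#include <Rcpp.h>
using namespace Rcpp;

// Direct-form-II-transposed IIR recursion with explicit initial state.
// b, a are filter coefficients (a[0] need not be 1); zi has length
// max(len(a), len(b)) - 1. Hot loop of the zero-phase filter, kept in C++
// because full-session traces (~6e4 samples) are filtered many times per run.
// [[Rcpp::export]]
NumericVector lfilter_cpp(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nf = std::max(nb, na);
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  double a0 = aa[0];
  if (a0 == 0.0) stop("a[1] must be nonzero");
  for (int i = 0; i < nf; ++i) { bb[i] /= a0; aa[i] /= a0; }

  std::vector<double> z(nf > 1 ? nf - 1 : 1, 0.0);
  for (int i = 0; i < nf - 1 && i < zi.size(); ++i) z[i] = zi[i];

  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nf > 1 ? z[0] : 0.0);
    for (int j = 0; j < nf - 2; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nf > 1)
      z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
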