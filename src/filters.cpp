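#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter applied column-wise.
// b, a: filter coefficients (a[0] must be 1); zi: (n-1) x ncol matrix of
// per-column initial state. Returns the filtered matrix.
// [[Rcpp::export]]
NumericMatrix df2t_filter_mat(NumericVector b, NumericVector a,
                              NumericMatrix X, NumericMatrix zi) {
  const int n = b.size();          // == a.size(), padded on the R side
  const int T = X.nrow(), C = X.ncol();
  if (a.size() != n) stop("b and a must have equal length");
  if (zi.nrow() != n - 1 || zi.ncol() != C) stop("zi has wrong dimensions");
  NumericMatrix Y(T, C);
  std::vector<double> z(n - 1);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < n - 1; ++j) z[j] = zi(j, c);
    for (int t = 0; t < T; ++t) {
      const double x = X(t, c);
      const double y = b[0] * x + z[0];
      for (int j = 0; j < n - 2; ++j)
        z[j] = b[j + 1] * x + z[j + 1] - a[j + 1] * y;
      z[n - 2] = b[n - 1] * x - a[n - 1] * y;
      Y(t, c) = y;
    }
  }
  return Y;
}
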