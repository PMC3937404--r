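#include <Rcpp.h>
using namespace Rcpp;

// 1-D convolution along the first dimension of a matrix with half-sample
// symmetric (mirror) boundary handling. Kernel length must be odd; the
// kernel is applied centred. Columns are independent signals.
// [[Rcpp::export]]
NumericMatrix conv_axis1_reflect(const NumericMatrix& x, const NumericVector& w) {
  const int n = x.nrow(), m = x.ncol(), K = w.size();
  if (K % 2 == 0) stop("kernel length must be odd");
  const int h = (K - 1) / 2;
  NumericMatrix out(n, m);
  // reflected source index for each tap position t = i + k, i in [0,n), k in [0,K)
  std::vector<int> idx(n + K - 1);
  const int p = 2 * n;
  for (int t = 0; t < n + K - 1; ++t) {
    int i = ((t - h) % p + p) % p;
    if (i >= n) i = p - 1 - i;
    idx[t] = i;
  }
  for (int j = 0; j < m; ++j) {
    const double* col = &x(0, j);
    double* o = &out(0, j);
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += w[k] * col[idx[i + k]];
      o[i] = s;
    }
  }
  return out;
}
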