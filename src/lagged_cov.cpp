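// Lagged covariance accumulation for SOBI. The pooled signal is long
// (millions of samples) and the estimate is needed for ~50 lags, so the
// shifted cross-products are accumulated in compiled code.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Direct-form II transposed IIR filter. Coefficients are normalized by
// a[0] on the R side; w0 carries the initial filter state (e.g. the
// steady-state response scaled by the first sample, so constants pass
// through exactly).
// [[Rcpp::export]]
Rcpp::NumericVector iir_filter_cpp(const Rcpp::NumericVector& b,
                                   const Rcpp::NumericVector& a,
                                   const Rcpp::NumericVector& x,
                                   const Rcpp::NumericVector& w0) {
  const int n = x.size();
  const int nb = b.size();
  const int na = a.size();
  const int nw = std::max(nb, na);
  std::vector<double> w(nw, 0.0);
  for (int k = 0; k < std::min<int>(w0.size(), nw); ++k) w[k] = w0[k];
  Rcpp::NumericVector y(n);
  for (int t = 0; t < n; ++t) {
    const double yt = b[0] * x[t] + w[0];
    for (int k = 1; k < nw; ++k) {
      const double bk = (k < nb) ? b[k] : 0.0;
      const double ak = (k < na) ? a[k] : 0.0;
      w[k - 1] = bk * x[t] - ak * yt + ((k < nw - 1) ? w[k] : 0.0);
    }
    y[t] = yt;
  }
  return y;
}

// X: dims x N, already row-mean-centered. bounds: segments x 2, 1-based
// inclusive column ranges; lagged products never straddle a boundary.
// [[Rcpp::export]]
arma::cube lagged_cov_cpp(const arma::mat& X, const arma::ivec& lags,
                          const arma::imat& bounds) {
  const arma::uword p = X.n_rows;
  arma::cube out(p, p, lags.n_elem, arma::fill::zeros);
  for (arma::uword k = 0; k < lags.n_elem; ++k) {
    const int tau = lags[k];
    arma::mat acc(p, p, arma::fill::zeros);
    double m = 0.0;
    for (arma::uword s = 0; s < bounds.n_rows; ++s) {
      const int a = bounds(s, 0) - 1;
      const int b = bounds(s, 1) - 1;
      const int len = b - a + 1;
      if (len <= tau) continue;
      acc += X.cols(a, b - tau) * X.cols(a + tau, b).t();
      m += len - tau;
    }
    acc /= m;
    out.slice(k) = (acc + acc.t()) / 2.0;
  }
  return out;
}
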