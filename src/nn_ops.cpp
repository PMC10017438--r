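// Fused elementwise kernels for the training loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::NumericVector relu_fwd_cpp(Rcpp::NumericVector x) {
  Rcpp::NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// gradient through ReLU using the stored output as mask (y > 0 <=> x > 0)
// [[Rcpp::export]]
Rcpp::NumericVector relu_bwd_cpp(Rcpp::NumericVector y,
                                 Rcpp::NumericVector gy) {
  Rcpp::NumericVector gx(y.size());
  for (R_xlen_t i = 0; i < y.size(); ++i) gx[i] = y[i] > 0 ? gy[i] : 0;
  gx.attr("dim") = gy.attr("dim");
  return gx;
}
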