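// 1D convolution primitives for the signal encoders.  Layout convention:
// activations are cubes (channels, length, batch); weights are matrices
// (out_channels, in_channels * kernel) so forward/backward reduce to GEMM
// against an im2col buffer.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline int out_len(int L, int k, int stride, int pad) {
  return (L + 2 * pad - k) / stride + 1;
}

static void im2col(const mat &xs, int k, int stride, int pad, mat &cols) {
  const int C = xs.n_rows, L = xs.n_cols;
  const int Lo = cols.n_cols;
  for (int t = 0; t < Lo; ++t) {
    const int base = t * stride - pad;
    for (int j = 0; j < k; ++j) {
      const int src = base + j;
      double *dst = cols.colptr(t) + (size_t)j * C;
      if (src >= 0 && src < L) {
        const double *s = xs.colptr(src);
        std::copy(s, s + C, dst);
      } else {
        std::fill(dst, dst + C, 0.0);
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv1d_fwd(const arma::cube &x, const arma::mat &w,
                      const arma::vec &b, int k, int stride, int pad) {
  const int C = x.n_rows, L = x.n_cols, N = x.n_slices;
  const int Co = w.n_rows;
  const int Lo = out_len(L, k, stride, pad);
  cube y(Co, Lo, N);
  mat cols((size_t)C * k, Lo);
  for (int n = 0; n < N; ++n) {
    im2col(x.slice(n), k, stride, pad, cols);
    y.slice(n) = w * cols;
    y.slice(n).each_col() += b;
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List conv1d_bwd(const arma::cube &x, const arma::mat &w,
                      const arma::cube &gy, int k, int stride, int pad) {
  const int C = x.n_rows, L = x.n_cols, N = x.n_slices;
  const int Lo = gy.n_cols;
  cube gx(C, L, N, fill::zeros);
  mat gw(w.n_rows, w.n_cols, fill::zeros);
  vec gb(w.n_rows, fill::zeros);
  mat cols((size_t)C * k, Lo);
  for (int n = 0; n < N; ++n) {
    im2col(x.slice(n), k, stride, pad, cols);
    const mat &g = gy.slice(n);
    gw += g * cols.t();
    gb += sum(g, 1);
    mat gcols = w.t() * g;                 // (C*k, Lo)
    mat &gxs = gx.slice(n);
    for (int t = 0; t < Lo; ++t) {
      const int base = t * stride - pad;
      for (int j = 0; j < k; ++j) {
        const int src = base + j;
        if (src < 0 || src >= L) continue;
        const double *s = gcols.colptr(t) + (size_t)j * C;
        double *dst = gxs.colptr(src);
        for (int c = 0; c < C; ++c) dst[c] += s[c];
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}
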