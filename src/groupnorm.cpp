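// Group normalization over (channels, length, batch) cubes: statistics are
// computed per sample and per channel group across (group channels x
// length), so normalization is batch-independent — identical in training
// and evaluation, which keeps streaming inference exactly equal to batch
// inference and avoids batch-composition leakage with contiguous
// sleep-epoch batches.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List gn_fwd_cpp(const arma::cube &x, const arma::vec &gamma,
                      const arma::vec &beta, int groups, double eps) {
  const uword C = x.n_rows, L = x.n_cols, N = x.n_slices;
  const uword G = (uword)groups, cg = C / G;
  cube xhat(size(x)), y(size(x));
  mat invstd(G, N);
  for (uword n = 0; n < N; ++n) {
    const mat &xs = x.slice(n);
    mat &hs = xhat.slice(n);
    mat &ys = y.slice(n);
    for (uword g = 0; g < G; ++g) {
      const uword c0 = g * cg, c1 = c0 + cg - 1;
      const double np = (double)cg * L;
      double s = 0.0, ss = 0.0;
      for (uword l = 0; l < L; ++l)
        for (uword c = c0; c <= c1; ++c) {
          const double v = xs(c, l);
          s += v; ss += v * v;
        }
      const double m = s / np;
      double var = ss / np - m * m;
      if (var < 0) var = 0;
      const double inv = 1.0 / std::sqrt(var + eps);
      invstd(g, n) = inv;
      for (uword l = 0; l < L; ++l)
        for (uword c = c0; c <= c1; ++c) {
          const double h = (xs(c, l) - m) * inv;
          hs(c, l) = h;
          ys(c, l) = gamma[c] * h + beta[c];
        }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("invstd") = invstd);
}

// [[Rcpp::export]]
Rcpp::List gn_bwd_cpp(const arma::cube &xhat, const arma::mat &invstd,
                      const arma::vec &gamma, const arma::cube &gy,
                      int groups) {
  const uword C = xhat.n_rows, L = xhat.n_cols, N = xhat.n_slices;
  const uword G = (uword)groups, cg = C / G;
  cube gx(size(xhat));
  vec ggamma(C, fill::zeros), gbeta(C, fill::zeros);
  for (uword n = 0; n < N; ++n) {
    const mat &hs = xhat.slice(n);
    const mat &gs = gy.slice(n);
    mat &go = gx.slice(n);
    for (uword g = 0; g < G; ++g) {
      const uword c0 = g * cg, c1 = c0 + cg - 1;
      const double np = (double)cg * L;
      double sum_gh = 0.0, sum_ghh = 0.0;
      for (uword l = 0; l < L; ++l)
        for (uword c = c0; c <= c1; ++c) {
          const double gxh = gs(c, l) * gamma[c];
          sum_gh += gxh;
          sum_ghh += gxh * hs(c, l);
          ggamma[c] += gs(c, l) * hs(c, l);
          gbeta[c] += gs(c, l);
        }
      const double inv = invstd(g, n);
      for (uword l = 0; l < L; ++l)
        for (uword c = c0; c <= c1; ++c) {
          const double gxh = gs(c, l) * gamma[c];
          go(c, l) = (inv / np) * (np * gxh - sum_gh - hs(c, l) * sum_ghh);
        }
    }
  }
  return Rcpp::List::create(Rcpp::Named("gx") = gx,
                            Rcpp::Named("ggamma") = ggamma,
                            Rcpp::Named("gbeta") = gbeta);
}
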