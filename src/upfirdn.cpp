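#include <Rcpp.h>
using namespace Rcpp;

// Centered polyphase upfirdn: upsample by p, FIR filter h, downsample by q,
// with the (len(h)-1)/2 group delay removed so output m corresponds to
// upsampled position m*q.
// [[Rcpp::export]]
NumericVector upfirdn_centered(NumericVector x, NumericVector h,
                               int p, int q, int n_out) {
  const int n = x.size(), nh = h.size();
  const long long D = (nh - 1) / 2;
  NumericVector y(n_out);
  for (int m = 0; m < n_out; ++m) {
    const long long pos = (long long)m * q + D;  // upsampled index
    // taps j with (pos - j) divisible by p and 0 <= (pos-j)/p < n
    long long j0 = pos % p;
    double acc = 0.0;
    for (long long j = j0; j < nh; j += p) {
      const long long i = (pos - j) / p;
      if (i >= 0 && i < n) acc += h[j] * x[i];
    }
    y[m] = acc;
  }
  return y;
}
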