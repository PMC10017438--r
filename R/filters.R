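# FIR design and resampling primitives.  The band-pass follows the common
# M/EEG convention: windowed-sinc (Hamming) linear-phase FIR whose length is
# 3.3 / (narrowest transition bandwidth) seconds, applied once and
# group-delay compensated ("one-pass, zero-phase").  Hamming gives the
# textbook 53 dB stopband attenuation and 0.0194 passband ripple.

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

hamming_win <- function(n) {
  m <- seq_len(n) - 1
  0.54 - 0.46 * cos(2 * pi * m / (n - 1))
}

kaiser_win <- function(n, beta = 5) {
  m <- seq_len(n) - 1
  r <- 2 * m / (n - 1) - 1
  besselI(beta * sqrt(pmax(1 - r^2, 0)), 0) / besselI(beta, 0)
}

# Hamming windowed-sinc band-pass.  Cutoffs sit mid-transition; length is
# 3.3 / min(transition bandwidth) seconds, forced odd.
design_bandpass_fir <- function(sfreq, l_freq, h_freq,
                                l_trans = NULL, h_trans = NULL) {
  nyq <- sfreq / 2
  if (!(l_freq > 0 && l_freq < h_freq && h_freq < nyq))
    stop("need 0 < l_freq < h_freq < Nyquist (", nyq, " Hz)")
  if (is.null(l_trans)) l_trans <- min(max(0.25 * l_freq, 2), l_freq)
  if (is.null(h_trans)) h_trans <- min(max(0.25 * h_freq, 2), nyq - h_freq)
  n <- ceiling(3.3 / min(l_trans, h_trans) * sfreq)
  if (n %% 2 == 0) n <- n + 1
  m <- seq_len(n) - 1 - (n - 1) / 2
  f1 <- (l_freq - l_trans / 2) / sfreq   # cycles/sample cutoffs
  f2 <- (h_freq + h_trans / 2) / sfreq
  h <- 2 * f2 * sinc(2 * f2 * m) - 2 * f1 * sinc(2 * f1 * m)
  h * hamming_win(n)
}

# FFT convolution with zero padding; returns the full linear convolution.
fft_conv <- function(x, h) {
  n <- length(x) + length(h) - 1
  nf <- stats::nextn(n, c(2, 3, 5))
  y <- Re(fft(fft(c(x, numeric(nf - length(x)))) *
              fft(c(h, numeric(nf - length(h)))), inverse = TRUE)) / nf
  y[seq_len(n)]
}

# One-pass zero-phase filtering: linear convolution then removal of the
# (len-1)/2 group delay on both sides; output length == input length.
fir_filt_zerophase <- function(x, h) {
  d <- (length(h) - 1) / 2
  fft_conv(x, h)[d + seq_along(x)]
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# best rational p/q ~= ratio with q bounded (continued fractions)
ratio_to_pq <- function(ratio, max_den = 10000L) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- ratio
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - ratio) < 1e-12 * ratio) break
    if (r - a < 1e-12) break
    r <- 1 / (r - a)
  }
  g <- gcd2(p1, q1)
  c(p = p1 / g, q = q1 / g)
}

#' Polyphase rational resampling
#'
#' Resamples `x` from `old_rate` to `new_rate` using upsample-filter-
#' downsample with an anti-aliasing Kaiser windowed-sinc low-pass (the
#' standard `resample_poly` scheme).  Exact when the rate ratio is rational.
#'
#' @param x numeric vector.
#' @param new_rate,old_rate sampling rates in Hz.
#' @return Resampled vector of length `floor(length(x) * p / q)` where
#'   `p/q` is the reduced rate ratio.
#' @export
resample_poly <- function(x, new_rate, old_rate) {
  if (abs(new_rate - old_rate) < 1e-12 * old_rate) return(x)
  pq <- ratio_to_pq(new_rate / old_rate)
  p <- pq[["p"]]; q <- pq[["q"]]
  mx <- max(p, q)
  n_taps <- as.integer(2 * 10 * mx + 1)
  m <- seq_len(n_taps) - 1 - (n_taps - 1) / 2
  fc <- 1 / (2 * mx)                       # cycles/sample at upsampled rate
  h <- 2 * fc * sinc(2 * fc * m) * kaiser_win(n_taps) * p
  n_out <- (length(x) * p) %/% q
  upfirdn_centered(as.numeric(x), h, as.integer(p), as.integer(q),
                   as.integer(n_out))
}
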