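# Neural-network primitives with hand-written forward/backward passes.
# Conventions:
#   * conv activations are arrays (channels, length, batch)
#   * dense activations are matrices (features, batch)
#   * every *_fwd returns list(y, cache); every *_bwd takes the cache and
#     the upstream gradient and accumulates parameter gradients into an
#     environment via acc_grad(), returning the input gradient.
# Gradient correctness is verified against central finite differences in
# the test suite.

new_grad_env <- function() new.env(parent = emptyenv())

acc_grad <- function(gr, name, val) {
  old <- gr[[name]]
  gr[[name]] <- if (is.null(old)) val else old + val
  invisible(NULL)
}

## ---- convolution (C++ GEMM kernels) ------------------------------------

conv_fwd <- function(params, prefix, x, k, stride, pad) {
  w <- params[[paste0(prefix, ".W")]]
  b <- params[[paste0(prefix, ".b")]]
  y <- conv1d_fwd(x, w, b, k, stride, pad)
  list(y = y, cache = list(x = x, k = k, stride = stride, pad = pad,
                           prefix = prefix))
}

conv_bwd <- function(params, cache, gy, gr) {
  w <- params[[paste0(cache$prefix, ".W")]]
  r <- conv1d_bwd(cache$x, w, gy, cache$k, cache$stride, cache$pad)
  acc_grad(gr, paste0(cache$prefix, ".W"), r$gw)
  acc_grad(gr, paste0(cache$prefix, ".b"), as.numeric(r$gb))
  r$gx
}

## ---- group normalization (per sample, per channel group) ---------------

GN_EPS <- 1e-5

# largest divisor of C giving a group size of about 8 channels
gn_groups <- function(C) {
  target <- max(1L, C %/% 8L)
  for (g in seq(target, 1L)) if (C %% g == 0L) return(g)
  1L
}

bn_fwd <- function(params, buffers, prefix, x, training) {
  g <- params[[paste0(prefix, ".gamma")]]
  b <- params[[paste0(prefix, ".beta")]]
  groups <- gn_groups(dim(x)[1])
  r <- gn_fwd_cpp(x, g, b, groups, GN_EPS)
  list(y = r$y, cache = list(xhat = r$xhat, invstd = r$invstd,
                             groups = groups, prefix = prefix))
}

bn_bwd <- function(params, cache, gy, gr) {
  g <- params[[paste0(cache$prefix, ".gamma")]]
  r <- gn_bwd_cpp(cache$xhat, cache$invstd, g, gy, cache$groups)
  acc_grad(gr, paste0(cache$prefix, ".gamma"), as.numeric(r$ggamma))
  acc_grad(gr, paste0(cache$prefix, ".beta"), as.numeric(r$gbeta))
  r$gx
}

## ---- elementwise -------------------------------------------------------

relu_fwd <- function(x) {
  y <- relu_fwd_cpp(x)
  list(y = y, cache = y)
}

relu_bwd <- function(cache, gy) relu_bwd_cpp(cache, gy)

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(y = x, cache = NULL))
  mask <- (runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(y = x * mask, cache = mask)
}

dropout_bwd <- function(cache, gy) if (is.null(cache)) gy else gy * cache

## ---- adaptive average pooling over the time axis -----------------------

pool_segments <- function(L, out_len) {
  starts <- floor((seq_len(out_len) - 1) * L / out_len) + 1
  ends <- ceiling(seq_len(out_len) * L / out_len)
  cbind(starts, ends)
}

adaptive_pool_fwd <- function(x, out_len) {
  d <- dim(x)
  seg <- pool_segments(d[2], out_len)
  y <- array(0, dim = c(d[1], out_len, d[3]))
  for (j in seq_len(out_len)) {
    sl <- x[, seg[j, 1]:seg[j, 2], , drop = FALSE]
    y[, j, ] <- colMeans(aperm(sl, c(2, 1, 3)))
  }
  list(y = y, cache = list(seg = seg, dims = d))
}

adaptive_pool_bwd <- function(cache, gy) {
  d <- cache$dims
  seg <- cache$seg
  gx <- array(0, dim = d)
  for (j in seq_len(nrow(seg))) {
    idx <- seg[j, 1]:seg[j, 2]
    g <- gy[, j, , drop = FALSE] / length(idx)   # (C, 1, N)
    gx[, idx, ] <- gx[, idx, , drop = FALSE] +
      aperm(array(g, dim = c(d[1], d[3], length(idx))), c(1, 3, 2))
  }
  gx
}

## ---- dense -------------------------------------------------------------

linear_fwd <- function(params, prefix, x) {
  w <- params[[paste0(prefix, ".W")]]
  b <- params[[paste0(prefix, ".b")]]
  list(y = w %*% x + b, cache = list(x = x, prefix = prefix))
}

linear_bwd <- function(params, cache, gy, gr) {
  w <- params[[paste0(cache$prefix, ".W")]]
  acc_grad(gr, paste0(cache$prefix, ".W"), tcrossprod(gy, cache$x))
  acc_grad(gr, paste0(cache$prefix, ".b"), rowSums(gy))
  crossprod(w, gy)
}

## ---- softmax / cross-entropy -------------------------------------------

log_softmax <- function(logits) {
  mx <- apply(logits, 2, max)
  z <- sweep(logits, 2, mx)
  sweep(z, 2, log(colSums(exp(z))))
}

## ---- GRU cell ----------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# params under `prefix`: Wi (3H x D), Wh (3H x H), bi, bh (3H).
# Gate order r, z, n (reset, update, candidate); x and h are matrices
# (D x B) and (H x B).
gru_fwd <- function(params, prefix, x, h) {
  wi <- params[[paste0(prefix, ".Wi")]]; wh <- params[[paste0(prefix, ".Wh")]]
  bi <- params[[paste0(prefix, ".bi")]]; bh <- params[[paste0(prefix, ".bh")]]
  H <- nrow(h)
  ai <- wi %*% x + bi
  ah <- wh %*% h + bh
  ir <- 1:H; iz <- (H + 1):(2 * H); inn <- (2 * H + 1):(3 * H)
  r <- sigmoid(ai[ir, , drop = FALSE] + ah[ir, , drop = FALSE])
  z <- sigmoid(ai[iz, , drop = FALSE] + ah[iz, , drop = FALSE])
  nn <- tanh(ai[inn, , drop = FALSE] + r * ah[inn, , drop = FALSE])
  h_new <- (1 - z) * nn + z * h
  list(y = h_new,
       cache = list(x = x, h = h, r = r, z = z, nn = nn,
                    ahn = ah[inn, , drop = FALSE], prefix = prefix))
}

# Returns list(gx, gh): gradients w.r.t. the step input and previous hidden.
gru_bwd <- function(params, cache, gh_new, gr) {
  p <- cache$prefix
  wi <- params[[paste0(p, ".Wi")]]; wh <- params[[paste0(p, ".Wh")]]
  r <- cache$r; z <- cache$z; nn <- cache$nn
  gn <- gh_new * (1 - z)
  gz <- gh_new * (cache$h - nn)
  gh <- gh_new * z
  gan <- gn * (1 - nn * nn)
  grr <- gan * cache$ahn
  gahn <- gan * r
  gaz <- gz * z * (1 - z)
  gar <- grr * r * (1 - r)
  gai <- rbind(gar, gaz, gan)
  gah <- rbind(gar, gaz, gahn)
  acc_grad(gr, paste0(p, ".Wi"), tcrossprod(gai, cache$x))
  acc_grad(gr, paste0(p, ".bi"), rowSums(gai))
  acc_grad(gr, paste0(p, ".Wh"), tcrossprod(gah, cache$h))
  acc_grad(gr, paste0(p, ".bh"), rowSums(gah))
  list(gx = crossprod(wi, gai), gh = gh + crossprod(wh, gah))
}
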