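# The three-stage classifier:
#   (1) per-signal 1D residual CNN encoders (EEG deep, EOG shallow) that map
#       a 2,560-sample epoch to a feature vector (1,280 by default),
#   (2) a three-layer mixer/compressor producing the 512-dim "mix" vector
#       shared by all channel permutations (absent signals are represented
#       by a learned missing-embedding so one parameter set serves every
#       permutation), and
#   (3) two heads: a context-free fully-connected classifier and a
#       bidirectional GRU context head, both emitting log-softmax over the
#       five stages (W, N1, N2, N3, REM).

#' Model configuration
#'
#' @param widths channel widths of the strided encoder stages.  Each stage
#'   downsamples time by its stride; the default five stride-2 stages reduce
#'   2,560 samples to 80 time points.
#' @param strides per-stage strides (same length as `widths`).
#' @param kernel_stem kernel of the first (stem) convolution.
#' @param kernel kernel of all other convolutions.
#' @param eeg_blocks,eog_blocks residual blocks following each downsampling
#'   stage (the EEG encoder is deep, the EOG encoder shallow).
#' @param pool_len adaptive-average-pool output length; the encoder feature
#'   length is `widths[last] * pool_len` (1,280 by default).
#' @param mix_len length of the compressed mix vector (512 by default); also
#'   the GRU hidden size per direction.
#' @param dropout_p dropout probability applied after dense/GRU layers
#'   during training.
#' @param input_len samples per input epoch (2,560).
#' @param n_classes number of sleep stages (5).
#' @return A list of class `model_config`.
#' @export
model_config <- function(widths = c(16, 32, 64, 128, 256),
                         strides = rep(2L, length(widths)),
                         kernel_stem = 7L, kernel = 3L,
                         eeg_blocks = 4L, eog_blocks = 1L,
                         pool_len = 5L, mix_len = 512L,
                         dropout_p = 0.5, input_len = 2560L,
                         n_classes = 5L) {
  stopifnot(length(widths) == length(strides), all(widths >= 1),
            all(strides >= 1), n_classes == 5L,
            dropout_p >= 0, dropout_p < 1)
  structure(list(widths = as.integer(widths), strides = as.integer(strides),
                 kernel_stem = as.integer(kernel_stem),
                 kernel = as.integer(kernel),
                 eeg_blocks = as.integer(eeg_blocks),
                 eog_blocks = as.integer(eog_blocks),
                 pool_len = as.integer(pool_len),
                 mix_len = as.integer(mix_len),
                 feature_len = as.integer(widths[length(widths)] * pool_len),
                 gru_hidden = as.integer(mix_len),
                 dropout_p = dropout_p, input_len = as.integer(input_len),
                 n_classes = 5L),
            class = "model_config")
}

#' Reduced, desk-scale model configuration
#'
#' A small variant (two downsampling stages of widths 8/16 with strides
#' 8/4, one residual block per stage, 64-dim mix vector) that trains in
#' minutes on one CPU; used throughout the test suite.
#'
#' @param ... overrides passed to [model_config()].
#' @export
reduced_model_config <- function(...) {
  args <- list(widths = c(8L, 16L), strides = c(8L, 4L),
               eeg_blocks = 1L, eog_blocks = 0L, mix_len = 64L,
               dropout_p = 0.25)
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}

## ---- parameter initialization ------------------------------------------

init_conv <- function(params, prefix, out_ch, in_ch, k) {
  fan_in <- in_ch * k
  params[[paste0(prefix, ".W")]] <-
    matrix(rnorm(out_ch * fan_in, sd = sqrt(2 / fan_in)), out_ch, fan_in)
  params[[paste0(prefix, ".b")]] <- numeric(out_ch)
}

init_bn <- function(params, buffers, prefix, ch) {
  params[[paste0(prefix, ".gamma")]] <- rep(1, ch)
  params[[paste0(prefix, ".beta")]] <- numeric(ch)
}

init_linear <- function(params, prefix, out_d, in_d, gain = 2) {
  params[[paste0(prefix, ".W")]] <-
    matrix(rnorm(out_d * in_d, sd = sqrt(gain / in_d)), out_d, in_d)
  params[[paste0(prefix, ".b")]] <- numeric(out_d)
}

init_gru <- function(params, prefix, in_d, h) {
  s <- 1 / sqrt(h)
  params[[paste0(prefix, ".Wi")]] <- matrix(runif(3 * h * in_d, -s, s), 3 * h, in_d)
  params[[paste0(prefix, ".Wh")]] <- matrix(runif(3 * h * h, -s, s), 3 * h, h)
  params[[paste0(prefix, ".bi")]] <- numeric(3 * h)
  params[[paste0(prefix, ".bh")]] <- numeric(3 * h)
}

init_encoder <- function(params, buffers, cfg, which) {
  prefix <- paste0("enc.", which)
  nb <- if (which == "eeg") cfg$eeg_blocks else cfg$eog_blocks
  in_ch <- 1L
  for (s in seq_along(cfg$widths)) {
    w <- cfg$widths[s]
    k <- if (s == 1) cfg$kernel_stem else cfg$kernel
    init_conv(params, sprintf("%s.s%d.conv", prefix, s), w, in_ch, k)
    init_bn(params, buffers, sprintf("%s.s%d.bn", prefix, s), w)
    for (j in seq_len(nb)) {
      for (half in 1:2) {
        init_conv(params, sprintf("%s.s%d.b%d.conv%d", prefix, s, j, half),
                  w, w, cfg$kernel)
        init_bn(params, buffers,
                sprintf("%s.s%d.b%d.bn%d", prefix, s, j, half), w)
      }
    }
    in_ch <- w
  }
}

#' Initialize a classifier model
#'
#' Draws fresh parameters from the current RNG state (callers seed the RNG
#' for reproducibility).
#'
#' @param cfg a [model_config()].
#' @param pre_cfg the [preprocess_config()] this model expects; its
#'   fingerprint is stored and checked at inference time.
#' @return A list of class `somnostage_model` with environments `params`
#'   and `buffers`.
#' @export
init_model <- function(cfg = model_config(), pre_cfg = preprocess_config()) {
  params <- new.env(parent = emptyenv())
  buffers <- new.env(parent = emptyenv())
  init_encoder(params, buffers, cfg, "eeg")
  init_encoder(params, buffers, cfg, "eog")
  f <- cfg$feature_len; m <- cfg$mix_len; h <- cfg$gru_hidden
  params[["miss.eeg"]] <- numeric(f)
  params[["miss.eog"]] <- numeric(f)
  init_linear(params, "mix.l1", f, 2L * f)
  init_linear(params, "mix.l2", m, f)
  init_linear(params, "mix.l3", m, m)
  init_linear(params, "cf.l1", m, m)
  init_linear(params, "cf.l2", m, m)
  init_linear(params, "cf.l3", m, m)
  init_linear(params, "cf.out", 5L, m, gain = 1)
  init_gru(params, "ctx.gru.f", m, h)
  init_gru(params, "ctx.gru.b", m, h)
  init_linear(params, "ctx.proj.f", m, h, gain = 1)
  init_linear(params, "ctx.proj.b", m, h, gain = 1)
  init_linear(params, "ctx.out", 5L, m, gain = 1)
  structure(list(cfg = cfg, pre_cfg = pre_cfg,
                 fingerprint = preprocess_fingerprint(pre_cfg),
                 params = params, buffers = buffers, version = 1L),
            class = "somnostage_model")
}

#' Number of trainable parameters
#' @param model a `somnostage_model`.
#' @export
n_params <- function(model) {
  sum(vapply(ls(model$params), function(n) length(model$params[[n]]),
             numeric(1)))
}

#' @export
print.somnostage_model <- function(x, ...) {
  cat(sprintf(
    "<somnostage_model> feature_len=%d mix_len=%d params=%s (%s)\n",
    x$cfg$feature_len, x$cfg$mix_len, format(n_params(x), big.mark = ","),
    x$fingerprint))
  invisible(x)
}

#' Save / load a trained model
#'
#' The checkpoint is a single-file archive holding the parameters, the model
#' and preprocessing configurations, and a version field; reloading gives
#' bit-identical outputs.
#'
#' @param model a `somnostage_model`.
#' @param path checkpoint path.
#' @export
save_model <- function(model, path) {
  obj <- list(version = model$version, cfg = model$cfg,
              pre_cfg = model$pre_cfg, fingerprint = model$fingerprint,
              params = as.list(model$params, sorted = TRUE),
              buffers = as.list(model$buffers, sorted = TRUE))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$version)) stop("not a somnostage checkpoint: ", path)
  params <- list2env(obj$params, parent = emptyenv())
  buffers <- list2env(obj$buffers, parent = emptyenv())
  structure(list(cfg = obj$cfg, pre_cfg = obj$pre_cfg,
                 fingerprint = obj$fingerprint,
                 params = params, buffers = buffers, version = obj$version),
            class = "somnostage_model")
}

## ---- encoder forward/backward ------------------------------------------

encoder_fwd <- function(model, x, which, training) {
  cfg <- model$cfg
  params <- model$params; buffers <- model$buffers
  prefix <- paste0("enc.", which)
  nb <- if (which == "eeg") cfg$eeg_blocks else cfg$eog_blocks
  stages <- vector("list", length(cfg$widths))
  h <- x
  for (s in seq_along(cfg$widths)) {
    k <- if (s == 1) cfg$kernel_stem else cfg$kernel
    cv <- conv_fwd(params, sprintf("%s.s%d.conv", prefix, s), h, k,
                   cfg$strides[s], (k - 1L) %/% 2L)
    bn <- bn_fwd(params, buffers, sprintf("%s.s%d.bn", prefix, s), cv$y,
                 training)
    rl <- relu_fwd(bn$y)
    h <- rl$y
    blocks <- vector("list", nb)
    for (j in seq_len(nb)) {
      p0 <- sprintf("%s.s%d.b%d", prefix, s, j)
      c1 <- conv_fwd(params, paste0(p0, ".conv1"), h, cfg$kernel, 1L,
                     (cfg$kernel - 1L) %/% 2L)
      b1 <- bn_fwd(params, buffers, paste0(p0, ".bn1"), c1$y, training)
      r1 <- relu_fwd(b1$y)
      c2 <- conv_fwd(params, paste0(p0, ".conv2"), r1$y, cfg$kernel, 1L,
                     (cfg$kernel - 1L) %/% 2L)
      b2 <- bn_fwd(params, buffers, paste0(p0, ".bn2"), c2$y, training)
      r2 <- relu_fwd(b2$y + h)
      blocks[[j]] <- list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                          c2 = c2$cache, b2 = b2$cache, r2 = r2$cache)
      h <- r2$y
    }
    stages[[s]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache,
                        blocks = blocks)
  }
  pl <- adaptive_pool_fwd(h, cfg$pool_len)
  n <- dim(x)[3]
  flat <- matrix(pl$y, nrow = cfg$feature_len, ncol = n)
  list(y = flat, cache = list(stages = stages, pool = pl$cache, n = n))
}

encoder_bwd <- function(model, cache, gflat, gr) {
  cfg <- model$cfg
  params <- model$params
  wlast <- cfg$widths[length(cfg$widths)]
  gy <- array(gflat, dim = c(wlast, cfg$pool_len, cache$n))
  g <- adaptive_pool_bwd(cache$pool, gy)
  for (s in rev(seq_along(cfg$widths))) {
    st <- cache$stages[[s]]
    for (j in rev(seq_along(st$blocks))) {
      bl <- st$blocks[[j]]
      g <- relu_bwd(bl$r2, g)
      gskip <- g
      g2 <- bn_bwd(params, bl$b2, g, gr)
      g2 <- conv_bwd(params, bl$c2, g2, gr)
      g1 <- relu_bwd(bl$r1, g2)
      g1 <- bn_bwd(params, bl$b1, g1, gr)
      g1 <- conv_bwd(params, bl$c1, g1, gr)
      g <- g1 + gskip
    }
    g <- relu_bwd(st$relu, g)
    g <- bn_bwd(params, st$bn, g, gr)
    g <- conv_bwd(params, st$conv, g, gr)
  }
  g
}

## ---- trunk (encoders + mixer) ------------------------------------------

trunk_fwd <- function(model, eeg, eog, training) {
  if (is.null(eeg) && is.null(eog))
    stop("at least one of the EEG/EOG inputs must be present")
  params <- model$params; cfg <- model$cfg
  n <- dim(if (!is.null(eeg)) eeg else eog)[3]
  enc_e <- if (!is.null(eeg)) encoder_fwd(model, eeg, "eeg", training)
  enc_o <- if (!is.null(eog)) encoder_fwd(model, eog, "eog", training)
  ve <- if (!is.null(enc_e)) enc_e$y else matrix(params[["miss.eeg"]],
                                                 cfg$feature_len, n)
  vo <- if (!is.null(enc_o)) enc_o$y else matrix(params[["miss.eog"]],
                                                 cfg$feature_len, n)
  x <- rbind(ve, vo)
  l1 <- linear_fwd(params, "mix.l1", x)
  r1 <- relu_fwd(l1$y)
  d1 <- dropout_fwd(r1$y, cfg$dropout_p, training)
  l2 <- linear_fwd(params, "mix.l2", d1$y)
  r2 <- relu_fwd(l2$y)
  d2 <- dropout_fwd(r2$y, cfg$dropout_p, training)
  l3 <- linear_fwd(params, "mix.l3", d2$y)
  list(y = l3$y,
       cache = list(enc_e = if (!is.null(enc_e)) enc_e$cache,
                    enc_o = if (!is.null(enc_o)) enc_o$cache,
                    l1 = l1$cache, r1 = r1$cache, d1 = d1$cache,
                    l2 = l2$cache, r2 = r2$cache, d2 = d2$cache,
                    l3 = l3$cache, n = n))
}

trunk_bwd <- function(model, cache, gmix, gr) {
  params <- model$params; cfg <- model$cfg
  g <- linear_bwd(params, cache$l3, gmix, gr)
  g <- dropout_bwd(cache$d2, g)
  g <- relu_bwd(cache$r2, g)
  g <- linear_bwd(params, cache$l2, g, gr)
  g <- dropout_bwd(cache$d1, g)
  g <- relu_bwd(cache$r1, g)
  gx <- linear_bwd(params, cache$l1, g, gr)
  f <- cfg$feature_len
  ge <- gx[seq_len(f), , drop = FALSE]
  go <- gx[f + seq_len(f), , drop = FALSE]
  if (!is.null(cache$enc_e)) encoder_bwd(model, cache$enc_e, ge, gr)
  else acc_grad(gr, "miss.eeg", rowSums(ge))
  if (!is.null(cache$enc_o)) encoder_bwd(model, cache$enc_o, go, gr)
  else acc_grad(gr, "miss.eog", rowSums(go))
  invisible(NULL)
}

## ---- context-free head -------------------------------------------------

cf_fwd <- function(model, mix, training) {
  params <- model$params; p <- model$cfg$dropout_p
  d0 <- dropout_fwd(mix, p, training)
  l1 <- linear_fwd(params, "cf.l1", d0$y); r1 <- relu_fwd(l1$y)
  d1 <- dropout_fwd(r1$y, p, training)
  l2 <- linear_fwd(params, "cf.l2", d1$y); r2 <- relu_fwd(l2$y)
  d2 <- dropout_fwd(r2$y, p, training)
  l3 <- linear_fwd(params, "cf.l3", d2$y); r3 <- relu_fwd(l3$y)
  d3 <- dropout_fwd(r3$y, p, training)
  lo <- linear_fwd(params, "cf.out", d3$y)
  list(logits = lo$y, logp = log_softmax(lo$y), penultimate = r3$y,
       cache = list(d0 = d0$cache, l1 = l1$cache, r1 = r1$cache,
                    d1 = d1$cache, l2 = l2$cache, r2 = r2$cache,
                    d2 = d2$cache, l3 = l3$cache, r3 = r3$cache,
                    d3 = d3$cache, lo = lo$cache))
}

cf_bwd <- function(model, cache, glogits, gr) {
  params <- model$params
  g <- linear_bwd(params, cache$lo, glogits, gr)
  g <- dropout_bwd(cache$d3, g)
  g <- relu_bwd(cache$r3, g)
  g <- linear_bwd(params, cache$l3, g, gr)
  g <- dropout_bwd(cache$d2, g)
  g <- relu_bwd(cache$r2, g)
  g <- linear_bwd(params, cache$l2, g, gr)
  g <- dropout_bwd(cache$d1, g)
  g <- relu_bwd(cache$r1, g)
  g <- linear_bwd(params, cache$l1, g, gr)
  dropout_bwd(cache$d0, g)
}

## ---- context head (GRU) ------------------------------------------------

# Runs the GRU over a contiguous sequence of mix vectors (columns of `mix`).
# `h0f`/`h0b` are initial hidden columns (H x 1); the backward direction is
# only used when `bidir` is TRUE.  The per-epoch context vector is
# proj.f %*% hf (+ proj.b %*% hb), length mix_len.
ctx_fwd_seq <- function(model, mix, h0f, h0b = NULL, training = FALSE,
                        bidir = TRUE) {
  params <- model$params; cfg <- model$cfg
  tlen <- ncol(mix)
  hsz <- cfg$gru_hidden
  dmix <- dropout_fwd(mix, cfg$dropout_p, training)
  hf <- matrix(0, hsz, tlen)
  fcaches <- vector("list", tlen)
  h <- h0f
  for (t in seq_len(tlen)) {
    st <- gru_fwd(params, "ctx.gru.f", dmix$y[, t, drop = FALSE], h)
    h <- st$y
    hf[, t] <- h
    fcaches[[t]] <- st$cache
  }
  hTf <- h
  v <- params[["ctx.proj.f.W"]] %*% hf + params[["ctx.proj.f.b"]]
  hb <- NULL; bcaches <- NULL; hTb <- NULL
  if (bidir) {
    hb <- matrix(0, hsz, tlen)
    bcaches <- vector("list", tlen)
    h <- if (is.null(h0b)) matrix(0, hsz, 1) else h0b
    for (t in rev(seq_len(tlen))) {
      st <- gru_fwd(params, "ctx.gru.b", dmix$y[, t, drop = FALSE], h)
      h <- st$y
      hb[, t] <- h
      bcaches[[t]] <- st$cache
    }
    hTb <- h
    v <- v + params[["ctx.proj.b.W"]] %*% hb + params[["ctx.proj.b.b"]]
  }
  dv <- dropout_fwd(v, cfg$dropout_p, training)
  lo <- linear_fwd(params, "ctx.out", dv$y)
  list(logits = lo$y, logp = log_softmax(lo$y), penultimate = v,
       hTf = hTf, hTb = hTb,
       cache = list(dmix = dmix$cache, hf = hf, hb = hb,
                    fcaches = fcaches, bcaches = bcaches,
                    h0f = h0f, h0b = h0b, dv = dv$cache, lo = lo$cache,
                    bidir = bidir, tlen = tlen))
}

ctx_bwd_seq <- function(model, cache, glogits, gr) {
  params <- model$params; cfg <- model$cfg
  tlen <- cache$tlen
  gv <- linear_bwd(params, cache$lo, glogits, gr)
  gv <- dropout_bwd(cache$dv, gv)
  # projection layers
  acc_grad(gr, "ctx.proj.f.W", gv %*% t(cache$hf))
  acc_grad(gr, "ctx.proj.f.b", rowSums(gv))
  ghf <- t(params[["ctx.proj.f.W"]]) %*% gv
  gmix <- matrix(0, cfg$mix_len, tlen)
  gh <- matrix(0, cfg$gru_hidden, 1)
  for (t in rev(seq_len(tlen))) {
    r <- gru_bwd(params, cache$fcaches[[t]], gh + ghf[, t, drop = FALSE], gr)
    gmix[, t] <- gmix[, t] + r$gx
    gh <- r$gh
  }
  if (cache$bidir) {
    acc_grad(gr, "ctx.proj.b.W", gv %*% t(cache$hb))
    acc_grad(gr, "ctx.proj.b.b", rowSums(gv))
    ghb <- t(params[["ctx.proj.b.W"]]) %*% gv
    gh <- matrix(0, cfg$gru_hidden, 1)
    for (t in seq_len(tlen)) {
      r <- gru_bwd(params, cache$bcaches[[t]], gh + ghb[, t, drop = FALSE], gr)
      gmix[, t] <- gmix[, t] + r$gx
      gh <- r$gh
    }
  }
  dropout_bwd(cache$dmix, gmix)
}

## ---- public, single-epoch operations -----------------------------------

as_epoch_array <- function(epoch, input_len) {
  if (is.null(dim(epoch))) {
    if (length(epoch) %% input_len != 0)
      stop("epoch length ", length(epoch), " is not a multiple of the ",
           "network input length ", input_len)
    epoch <- array(epoch, dim = c(1, input_len, length(epoch) %/% input_len))
  }
  d <- dim(epoch)
  if (length(d) != 3 || d[1] != 1 || d[2] != input_len)
    stop("expected input of shape 1 x ", input_len, " x n_epochs")
  if (!all(is.finite(epoch))) stop("non-finite values in network input")
  epoch
}

#' Encode a preprocessed epoch with a signal encoder
#'
#' Runs the EEG or EOG residual encoder in evaluation mode.
#'
#' @param model a `somnostage_model`.
#' @param epoch numeric vector of `input_len` (2,560) samples, or an array
#'   `1 x input_len x n`.
#' @param which `"eeg"` or `"eog"`.
#' @return A feature matrix `feature_len x n` (a vector's worth per epoch).
#' @export
encode_signal <- function(model, epoch, which = c("eeg", "eog")) {
  which <- match.arg(which)
  x <- as_epoch_array(epoch, model$cfg$input_len)
  encoder_fwd(model, x, which, training = FALSE)$y
}

#' Mix/compress encoder features into the shared representation
#'
#' @param model a `somnostage_model`.
#' @param eeg_vec,eog_vec feature matrices (`feature_len x n`) or `NULL`
#'   when that signal is absent (at least one must be present).
#' @return Mix matrix `mix_len x n`.
#' @export
mix_compress <- function(model, eeg_vec = NULL, eog_vec = NULL) {
  if (is.null(eeg_vec) && is.null(eog_vec))
    stop("at least one of eeg_vec/eog_vec must be present")
  params <- model$params; cfg <- model$cfg
  as_mat <- function(v) {
    if (is.null(v)) return(NULL)
    v <- as.matrix(v)
    if (nrow(v) != cfg$feature_len)
      stop("feature vector length ", nrow(v), " != feature_len ",
           cfg$feature_len)
    v
  }
  eeg_vec <- as_mat(eeg_vec); eog_vec <- as_mat(eog_vec)
  n <- ncol(if (!is.null(eeg_vec)) eeg_vec else eog_vec)
  ve <- if (!is.null(eeg_vec)) eeg_vec else matrix(params[["miss.eeg"]],
                                                   cfg$feature_len, n)
  vo <- if (!is.null(eog_vec)) eog_vec else matrix(params[["miss.eog"]],
                                                   cfg$feature_len, n)
  x <- rbind(ve, vo)
  h <- relu_fwd(linear_fwd(params, "mix.l1", x)$y)$y
  h <- relu_fwd(linear_fwd(params, "mix.l2", h)$y)$y
  linear_fwd(params, "mix.l3", h)$y
}

#' Context-free stage head
#'
#' @param model a `somnostage_model`.
#' @param mix mix matrix `mix_len x n` (or vector of `mix_len`).
#' @return Matrix `5 x n` of log-probabilities (stage order W, N1, N2, N3,
#'   REM); each column exp-sums to 1.
#' @export
head_context_free <- function(model, mix) {
  mix <- as.matrix(mix)
  if (nrow(mix) != model$cfg$mix_len)
    stop("mix vector length ", nrow(mix), " != mix_len ", model$cfg$mix_len)
  out <- cf_fwd(model, mix, training = FALSE)
  structure(out$logp, dimnames = list(STAGES, NULL))
}

#' Zero-initialized GRU hidden state
#' @param model a `somnostage_model`.
#' @return A list of class `gru_hidden` with forward (and backward) state
#'   columns set to zero and `cursor = 0`.
#' @export
zero_hidden <- function(model) {
  h <- model$cfg$gru_hidden
  structure(list(fwd = matrix(0, h, 1), bwd = matrix(0, h, 1), cursor = 0L),
            class = "gru_hidden")
}

#' Context-aware stage head (one step, forward direction)
#'
#' @param model a `somnostage_model`.
#' @param mix one mix vector (`mix_len`).
#' @param hidden a [zero_hidden()] state (or `NULL` for zero-init).
#' @return List with `log_probs` (length-5, exp-sums to 1) and the updated
#'   `hidden`.
#' @export
head_context <- function(model, mix, hidden = NULL) {
  mix <- matrix(mix, ncol = 1)
  if (nrow(mix) != model$cfg$mix_len)
    stop("mix vector length ", nrow(mix), " != mix_len ", model$cfg$mix_len)
  if (is.null(hidden)) hidden <- zero_hidden(model)
  if (!inherits(hidden, "gru_hidden") ||
      nrow(hidden$fwd) != model$cfg$gru_hidden)
    stop("hidden state shape does not match the model configuration")
  out <- ctx_fwd_seq(model, mix, h0f = hidden$fwd, training = FALSE,
                     bidir = FALSE)
  hidden$fwd <- out$hTf
  hidden$cursor <- hidden$cursor + 1L
  list(log_probs = setNames(as.numeric(out$logp), STAGES), hidden = hidden)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
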