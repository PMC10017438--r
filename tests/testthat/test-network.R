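test_that("architecture contracts hold for the default configuration", {
  set.seed(41)
  model <- init_model(model_config())
  expect_identical(model$cfg$feature_len, 1280L)
  expect_identical(model$cfg$mix_len, 512L)
  x <- array(rnorm(2560 * 2), c(1, 2560, 2))
  fe <- encode_signal(model, x, "eeg")
  fo <- encode_signal(model, x, "eog")
  expect_identical(dim(fe), c(1280L, 2L))
  expect_identical(dim(fo), c(1280L, 2L))
  mix <- mix_compress(model, fe, fo)
  expect_identical(dim(mix), c(512L, 2L))
  # single-signal pathways share the same parameter set
  expect_identical(dim(mix_compress(model, eeg_vec = fe)), c(512L, 2L))
  expect_identical(dim(mix_compress(model, eog_vec = fo)), c(512L, 2L))
  lp <- head_context_free(model, mix)
  expect_identical(dim(lp), c(5L, 2L))
  expect_equal(colSums(exp(lp)), c(1, 1), tolerance = 1e-6)
  ctx <- head_context(model, mix[, 1], zero_hidden(model))
  expect_length(ctx$log_probs, 5)
  expect_equal(sum(exp(ctx$log_probs)), 1, tolerance = 1e-6)
  expect_identical(dim(ctx$hidden$fwd), c(512L, 1L))
  expect_identical(ctx$hidden$cursor, 1L)
})

test_that("encoders are deterministic in eval mode and validate shapes", {
  model <- tiny_model()
  x <- array(rnorm(64 * 3), c(1, 64, 3))
  a <- encode_signal(model, x, "eeg")
  b <- encode_signal(model, x, "eeg")
  expect_identical(a, b)
  z <- encode_signal(model, array(0, c(1, 64, 1)), "eeg")
  expect_true(all(is.finite(z)))
  expect_error(encode_signal(model, rnorm(63), "eeg"), "multiple")
  expect_error(mix_compress(model), "at least one")
  expect_error(head_context_free(model, matrix(0, 3, 1)), "mix_len")
  expect_error(head_context(model, rnorm(6),
                            structure(list(fwd = matrix(0, 3, 1)),
                                      class = "gru_hidden")),
               "hidden")
})

test_that("zeroed final layer yields the uniform distribution", {
  model <- tiny_model()
  model$params[["cf.out.W"]][] <- 0
  model$params[["cf.out.b"]][] <- 0
  lp <- head_context_free(model, matrix(rnorm(6), 6, 1))
  expect_equal(as.numeric(exp(lp)), rep(0.2, 5), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences everywhere", {
  set.seed(43)
  model <- tiny_model(seed = 43)
  B <- 3
  eeg <- array(rnorm(64 * B), c(1, 64, B))
  eog <- array(rnorm(64 * B), c(1, 64, B))
  targets <- c(1L, 3L, 5L)
  w <- c(W = 1, N1 = 2.4, N2 = 1, N3 = 1.2, REM = 1.4)
  hf <- matrix(0.1, 6, 1); hb <- matrix(-0.05, 6, 1)

  loss_fn <- function(use_eeg, use_eog) {
    tr <- ns$trunk_fwd(model, if (use_eeg) eeg, if (use_eog) eog,
                       training = TRUE)
    cf <- ns$cf_fwd(model, tr$y, training = TRUE)
    cx <- ns$ctx_fwd_seq(model, tr$y, h0f = hf, h0b = hb, training = TRUE,
                         bidir = TRUE)
    weighted_cross_entropy(cf$logp, targets, w) +
      weighted_cross_entropy(cx$logp, targets, w)
  }
  for (case in list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE))) {
    gr <- ns$new_grad_env()
    tr <- ns$trunk_fwd(model, if (case[1]) eeg, if (case[2]) eog,
                       training = TRUE)
    cf <- ns$cf_fwd(model, tr$y, training = TRUE)
    cx <- ns$ctx_fwd_seq(model, tr$y, h0f = hf, h0b = hb, training = TRUE,
                         bidir = TRUE)
    gmix <- ns$cf_bwd(model, cf$cache,
                      ns$wce_grad_logits(cf$logp, targets, w), gr) +
            ns$ctx_bwd_seq(model, cx$cache,
                           ns$wce_grad_logits(cx$logp, targets, w), gr)
    ns$trunk_bwd(model, tr$cache, gmix, gr)
    set.seed(17)
    for (name in ls(gr)) {
      p <- model$params[[name]]
      g <- gr[[name]]
      for (i in sample(length(p), min(2, length(p)))) {
        eps <- 1e-5
        model$params[[name]][i] <- p[i] + eps
        lp <- loss_fn(case[1], case[2])
        model$params[[name]][i] <- p[i] - eps
        lm <- loss_fn(case[1], case[2])
        model$params[[name]][i] <- p[i]
        num <- (lp - lm) / (2 * eps)
        expect_lt(abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])), 1e-3,
                  label = paste("grad", name))
      }
    }
  }
})

test_that("gradient reaches every trainable tensor across the permutations", {
  model <- tiny_model(seed = 44)
  w <- c(W = 1, N1 = 2.4, N2 = 1, N3 = 1.2, REM = 1.4)
  seen <- character()
  for (case in list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE))) {
    gr <- ns$new_grad_env()
    eeg <- if (case[1]) array(rnorm(64 * 2), c(1, 64, 2))
    eog <- if (case[2]) array(rnorm(64 * 2), c(1, 64, 2))
    tr <- ns$trunk_fwd(model, eeg, eog, training = TRUE)
    cf <- ns$cf_fwd(model, tr$y, training = TRUE)
    cx <- ns$ctx_fwd_seq(model, tr$y, h0f = matrix(0, 6, 1),
                         h0b = matrix(0, 6, 1), training = TRUE, bidir = TRUE)
    targets <- c(2L, 4L)
    gmix <- ns$cf_bwd(model, cf$cache,
                      ns$wce_grad_logits(cf$logp, targets, w), gr) +
            ns$ctx_bwd_seq(model, cx$cache,
                           ns$wce_grad_logits(cx$logp, targets, w), gr)
    ns$trunk_bwd(model, tr$cache, gmix, gr)
    seen <- union(seen, ls(gr))
  }
  expect_setequal(seen, ls(model$params))
})

test_that("model parameter count is reported and save/load is bit-exact", {
  model <- tiny_model(seed = 45)
  expect_true(is.finite(n_params(model)) && n_params(model) > 0)
  x <- array(rnorm(64 * 2), c(1, 64, 2))
  before <- head_context_free(model, mix_compress(
    model, encode_signal(model, x, "eeg")))
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(model, path)
  back <- load_model(path)
  after <- head_context_free(back, mix_compress(
    back, encode_signal(back, x, "eeg")))
  expect_identical(before, after)
  expect_identical(back$fingerprint, model$fingerprint)
})

test_that("stage distributions stay normalized through both heads", {
  model <- tiny_model(seed = 46)
  mix <- matrix(rnorm(6 * 7), 6, 7)
  lp1 <- head_context_free(model, mix)
  expect_equal(colSums(exp(lp1)), rep(1, 7), tolerance = 1e-9)
  h <- NULL
  for (i in 1:7) {
    out <- head_context(model, mix[, i], h)
    h <- out$hidden
    expect_equal(sum(exp(out$log_probs)), 1, tolerance = 1e-9)
  }
  expect_identical(h$cursor, 7L)
})
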