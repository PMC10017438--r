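small_trained_model <- function() {
  if (is.null(.fixture_env$trained_small)) {
    psgs <- fixture_psgs(5, 60, seed = 501)
    tcfg <- reduced_train_config(n_epochs = 2, seed = 53)
    set.seed(tcfg$seed)
    model <- init_model(reduced_model_config(), preprocess_config())
    opt <- ns$new_adamw_state()
    train_epoch(model, psgs, tcfg, opt)
    train_epoch(model, psgs, tcfg, opt)
    .fixture_env$trained_small <- model
  }
  .fixture_env$trained_small
}

test_that("certainty is the cross-entropy against the inferred stage", {
  expect_equal(certainty(rep(log(0.2), 5)), log(5), tolerance = 1e-12)
  degenerate <- c(0, rep(-1e9, 4))
  expect_equal(certainty(degenerate), 0)
  # strictly decreasing in the argmax probability
  ps <- seq(0.21, 0.99, by = 0.02)
  vals <- vapply(ps, function(p) {
    certainty(log(c(p, rep((1 - p) / 4, 4))))
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_error(certainty(c(NA, 1, 1, 1, 1)), "non-finite")
})

test_that("all three modes return one stage per epoch and normalized probs", {
  model <- small_trained_model()
  psg <- fixture_psgs(1, 12, seed = 601)[[1]]
  perm <- signal_permutation("C3", TRUE)
  for (mode in c("bidirectional", "forward", "context_free")) {
    res <- infer(model, psg$epochs, perm, mode)
    expect_length(res$hypnogram, 12)
    expect_identical(dim(res$log_probs), c(5L, 12L))
    expect_equal(colSums(exp(res$log_probs)), rep(1, 12), tolerance = 1e-6)
    expect_true(all(res$certainties >= 0))
    expect_identical(res$mode, mode)
    # argmax consistency with the tie rule
    expect_identical(as.character(res$hypnogram),
                     STAGES[apply(res$log_probs, 2, which.max)])
  }
  # single-epoch input works in every mode
  one <- psg$epochs
  one$data <- one$data[, , 1, drop = FALSE]
  for (mode in c("bidirectional", "forward", "context_free"))
    expect_length(infer(model, one, perm, mode)$hypnogram, 1)
})

test_that("argmax ties break toward the lower stage index", {
  lp <- log(matrix(c(0.3, 0.3, 0.2, 0.1, 0.1), 5, 1))
  res <- ns$new_inference_result(lp, "X", "context_free")
  expect_identical(as.character(res$hypnogram), "W")
})

test_that("streaming inference equals batch forward inference", {
  model <- small_trained_model()
  psg <- fixture_psgs(1, 40, seed = 602)[[1]]
  perm <- signal_permutation("C3", TRUE)
  batch <- infer(model, psg$epochs, perm, "forward")
  inp <- apply_permutation(psg$epochs, perm)
  hidden <- NULL
  for (t in seq_len(40)) {
    step <- stream_step(model,
                        list(eeg = inp$eeg[, , t], eog = inp$eog[, , t]),
                        hidden)
    hidden <- step$hidden
    expect_lt(max(abs(step$log_probs - batch$log_probs[, t])), 1e-5)
    expect_true(step$latency_s >= 0)
  }
  expect_identical(hidden$cursor, 40L)
})

test_that("first streaming call uses the all-zero state", {
  model <- small_trained_model()
  psg <- fixture_psgs(1, 12, seed = 601)[[1]]
  inp <- apply_permutation(psg$epochs, signal_permutation("C3", TRUE))
  ep1 <- list(eeg = inp$eeg[, , 1], eog = inp$eog[, , 1])
  a <- stream_step(model, ep1, NULL)
  b <- stream_step(model, ep1, zero_hidden(model))
  expect_equal(a$log_probs, b$log_probs, tolerance = 1e-12)
  expect_error(stream_step(model, list()), "at least one")
})

test_that("consensus picks the most certain permutation per epoch", {
  set.seed(603)
  lp_conf <- ns$log_softmax(matrix(rnorm(25) * 0.1, 5))  # near-uniform
  r1 <- ns$new_inference_result(lp_conf, "A", "bidirectional")
  lp_sharp <- log(matrix(rep(c(0.9, rep(0.025, 4)), 5), 5))
  r2 <- ns$new_inference_result(lp_sharp, "B", "bidirectional")
  cons <- consensus(list(r1, r2))
  expect_identical(cons$permutation, "CONSENSUS")
  expect_identical(unique(cons$source_permutation), "B")
  expect_equal(cons$log_probs, r2$log_probs)

  # identity on a single permutation
  solo <- consensus(list(r1))
  expect_equal(solo$log_probs, r1$log_probs)
  expect_identical(as.character(solo$hypnogram), as.character(r1$hypnogram))

  expect_error(consensus(list()), "no inference")
  short <- ns$new_inference_result(lp_conf[, 1:3], "C", "bidirectional")
  expect_error(consensus(list(r1, short)), "mismatched epoch")
  other <- ns$new_inference_result(lp_conf, "D", "forward")
  expect_error(consensus(list(r1, other)), "mismatched modes")
})

test_that("consensus equals the brute-force argmin over certainties", {
  for (seed in 1:20) {
    results <- lapply(1:6, function(k)
      ns$new_inference_result(random_logp(100, seed = 1000 * seed + k),
                              paste0("P", k), "context_free"))
    cons <- consensus(results)
    cert <- sapply(results, `[[`, "certainties")  # 100 x 6
    for (i in seq_len(100)) {
      best <- which.min(cert[i, ])
      expect_identical(cons$log_probs[, i], results[[best]]$log_probs[, i])
    }
    # never selects a permutation with strictly larger certainty
    expect_true(all(cons$certainties <= apply(cert, 1, min) + 1e-12))
  }
})

test_that("latent extraction yields three aligned mix_len streams", {
  model <- small_trained_model()
  psg <- fixture_psgs(1, 12, seed = 601)[[1]]
  perm <- signal_permutation("C3", TRUE)
  lat <- extract_latents(model, psg$epochs, perm)
  m <- model$cfg$mix_len
  for (nm in c("mixer", "cf_penultimate", "ctx_penultimate")) {
    expect_identical(dim(lat[[nm]]), c(m, 12L), label = nm)
    expect_true(all(is.finite(lat[[nm]])))
  }
  # mixer latents agree with a standalone trunk evaluation
  inp <- apply_permutation(psg$epochs, perm)
  mix <- ns$trunk_eval(model, inp)
  expect_equal(lat$mixer, mix, tolerance = 1e-12)
})

test_that("preprocessing fingerprints are enforced", {
  model <- small_trained_model()
  psg <- fixture_psgs(1, 12, seed = 601)[[1]]
  ep <- psg$epochs
  ep$fingerprint <- "bp0.5-45;spe2560;el30;filt1"
  expect_error(infer(model, ep, signal_permutation("C3", TRUE)),
               "fingerprint")
})

test_that("montage-level consensus adopts the most certain view per epoch", {
  model <- small_trained_model()
  psg <- fixture_psgs(1, 30, seed = 604)[[1]]
  perms <- ns$perms_for_epochs(psg$epochs, polarity_flips = FALSE)
  views <- lapply(perms, function(p) infer(model, psg$epochs, p,
                                           "bidirectional"))
  cons <- infer_consensus(model, psg$epochs, "bidirectional",
                          polarity_flips = FALSE)
  expect_length(cons$hypnogram, 30)
  expect_true(all(cons$source_permutation %in%
                    vapply(perms, format, character(1))))
  cert <- sapply(views, `[[`, "certainties")
  expect_equal(cons$certainties, apply(cert, 1, min), tolerance = 1e-12)
})
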