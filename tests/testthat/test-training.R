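test_that("weighted cross-entropy reproduces hand-computed values", {
  unif <- matrix(log(0.2), 5, 1)
  # weights cancel under weighted-mean reduction
  expect_equal(weighted_cross_entropy(unif, "N1"), log(5), tolerance = 1e-12)
  expect_equal(weighted_cross_entropy(unif, "W"), log(5), tolerance = 1e-12)
  # unreduced per-sample term carries the N1 weight 2.4
  expect_equal(weighted_cross_entropy(unif, "N1", reduce = FALSE),
               2.4 * log(5), tolerance = 1e-12)
  # perfect prediction has zero loss
  perfect <- matrix(c(0, rep(-Inf, 4)), 5, 1)
  expect_equal(weighted_cross_entropy(perfect, "W"), 0)
  expect_error(weighted_cross_entropy(unif, "UNKNOWN"), "mask")
  expect_error(weighted_cross_entropy(unif, c("W", "N1")), "batch size")
})

test_that("weighted cross-entropy matches a scalar-loop oracle", {
  w <- c(W = 1, N1 = 2.4, N2 = 1, N3 = 1.2, REM = 1.4)
  lp <- random_logp(64, seed = 51)
  targets <- sample(STAGES, 64, TRUE)
  expect_equal(weighted_cross_entropy(lp, targets, w),
               oracle_wce(lp, targets, w), tolerance = 1e-6)
  # gradient of the reduction sums to zero over classes per sample
  g <- ns$wce_grad_logits(lp, match(targets, STAGES), w)
  expect_lt(max(abs(colSums(g))), 1e-12)
})

test_that("make_batches partitions contiguously with near-equal sizes", {
  b <- make_batches(1280, 128)
  expect_length(b, 128)
  expect_true(all(lengths(b) == 10))
  expect_identical(unlist(b), 1:1280)

  b2 <- make_batches(1285, 128)
  expect_true(all(lengths(b2) %in% c(10, 11)))
  expect_identical(sum(lengths(b2)), 1285L)
  expect_identical(unlist(b2), 1:1285)

  expect_identical(make_batches(5, 1), list(1:5))
  expect_message(b3 <- make_batches(5, 128), "reducing")
  expect_length(b3, 5)
  expect_error(make_batches(0, 4), "empty")
})

test_that("checkpoint selection ranks by MCC + F1 rank sum", {
  hist <- list(list(mcc = 0.5, f1_macro = 0.6),
               list(mcc = 0.7, f1_macro = 0.5),
               list(mcc = 0.6, f1_macro = 0.7))
  expect_identical(select_checkpoints(hist, 2), c(3L, 2L))
  expect_setequal(select_checkpoints(hist, 3), 1:3)
  # dominance: an epoch best on both metrics ranks first
  hist2 <- list(list(mcc = 0.4, f1_macro = 0.4),
                list(mcc = 0.9, f1_macro = 0.9),
                list(mcc = 0.5, f1_macro = 0.3))
  expect_identical(select_checkpoints(hist2, 1), 2L)
  # ties go to the later epoch
  hist3 <- list(list(mcc = 0.5, f1_macro = 0.5),
                list(mcc = 0.5, f1_macro = 0.5))
  expect_identical(select_checkpoints(hist3, 1), 2L)
  expect_error(select_checkpoints(hist, 4), "cannot select")
  expect_error(select_checkpoints(list(), 1), "empty")
})

test_that("weight averaging is an elementwise mean with convex norms", {
  m <- tiny_model(seed = 52)
  ck1 <- ns$snapshot_checkpoint(m, 1)
  ck2 <- ck1; ck3 <- ck1
  for (nm in names(ck2$params)) {
    ck2$params[[nm]] <- ck1$params[[nm]] + 1
    ck3$params[[nm]] <- -ck1$params[[nm]]
  }
  # identical checkpoints average to themselves
  same <- average_weights(list(ck1, ck1))
  expect_equal(same$params, ck1$params)
  # w and -w average to zero
  zero <- average_weights(list(ck1, ck3))
  expect_true(all(vapply(zero$params, function(p) max(abs(p)), numeric(1))
                  < 1e-12))
  # three checkpoints match an independent elementwise mean
  avg <- average_weights(list(ck1, ck2, ck3))
  for (nm in names(ck1$params)) {
    manual <- (ck1$params[[nm]] + ck2$params[[nm]] + ck3$params[[nm]]) / 3
    expect_equal(avg$params[[nm]], manual, tolerance = 1e-12)
    # convexity: averaged norm bounded by the max input norm
    expect_lte(sqrt(sum(avg$params[[nm]]^2)),
               max(sqrt(sum(ck1$params[[nm]]^2)),
                   sqrt(sum(ck2$params[[nm]]^2)),
                   sqrt(sum(ck3$params[[nm]]^2))) + 1e-12)
  }
  bad <- ck2
  bad$params[[1]] <- matrix(0, 2, 2)
  expect_error(average_weights(list(ck1, bad)), "shape mismatch")
})

test_that("training reduces the loss on a small synthetic set", {
  # scaled-down version of the learning check (the full 50-night, 5-epoch,
  # 3-seed run lives in the acceptance suite)
  psgs <- fixture_psgs(5, 60, seed = 501)
  tcfg <- reduced_train_config(n_epochs = 2, seed = 53)
  set.seed(tcfg$seed)
  model <- init_model(reduced_model_config(), preprocess_config())
  opt <- ns$new_adamw_state()
  l1 <- train_epoch(model, psgs, tcfg, opt)$loss
  l2 <- train_epoch(model, psgs, tcfg, opt)$loss
  expect_lt(l2, l1)
  .fixture_env$trained_small <- model   # reused by inference tests
})

test_that("training is reproducible under a fixed seed", {
  psgs <- fixture_psgs(2, 20, seed = 502)
  tcfg <- reduced_train_config(n_epochs = 1, seed = 54)
  f1 <- fit_model(psgs, tcfg = tcfg, mcfg = tiny_model_config(0.25))
  f2 <- fit_model(psgs, tcfg = tcfg, mcfg = tiny_model_config(0.25))
  p1 <- as.list(f1$model$params, sorted = TRUE)
  p2 <- as.list(f2$model$params, sorted = TRUE)
  expect_identical(p1, p2)
})

test_that("validation-driven checkpoint averaging is wired into fit_model", {
  psgs <- fixture_psgs(2, 20, seed = 502)
  tcfg <- reduced_train_config(n_epochs = 3, seed = 57)
  fit <- fit_model(psgs, val_psgs = psgs[1], tcfg = tcfg,
                   mcfg = tiny_model_config(0.25), select_k = 2)
  expect_length(fit$selected, 2)
  expect_length(fit$history, 3)
  expect_true(all(vapply(fit$history, function(h) is.finite(h$mcc),
                         logical(1))))
})

test_that("UNKNOWN epochs are masked out of the loss but not the context", {
  psgs <- fixture_psgs(1, 20, seed = 503)
  h <- unclass(psgs[[1]]$hypnogram)
  h[5:8] <- "UNKNOWN"
  psgs[[1]]$hypnogram <- new_hypnogram(h)
  tcfg <- reduced_train_config(n_epochs = 1, seed = 55)
  set.seed(tcfg$seed)
  model <- init_model(reduced_model_config(), preprocess_config())
  out <- train_epoch(model, psgs, tcfg, ns$new_adamw_state())
  expect_true(is.finite(out$loss))
})

test_that("context-free gradients are unchanged by disabling the context head", {
  # additivity of backprop: trunk gradient from the CF head alone is the
  # same whether or not the context head's gradient is also accumulated
  model <- tiny_model(seed = 56)
  w <- c(W = 1, N1 = 2.4, N2 = 1, N3 = 1.2, REM = 1.4)
  eeg <- array(rnorm(64 * 2), c(1, 64, 2))
  targets <- c(1L, 2L)
  run <- function(with_ctx) {
    gr <- ns$new_grad_env()
    tr <- ns$trunk_fwd(model, eeg, NULL, training = TRUE)
    cf <- ns$cf_fwd(model, tr$y, training = TRUE)
    gmix <- ns$cf_bwd(model, cf$cache,
                      ns$wce_grad_logits(cf$logp, targets, w), gr)
    if (with_ctx) {
      cx <- ns$ctx_fwd_seq(model, tr$y, h0f = matrix(0, 6, 1),
                           h0b = matrix(0, 6, 1), training = TRUE,
                           bidir = TRUE)
      gmix <- gmix + ns$ctx_bwd_seq(model, cx$cache,
                                    ns$wce_grad_logits(cx$logp, targets, w),
                                    gr)
    }
    ns$trunk_bwd(model, tr$cache, gmix, gr)
    gr
  }
  g_with <- run(TRUE)
  g_without <- run(FALSE)
  # CF head parameters receive identical gradients either way
  expect_equal(g_with[["cf.l1.W"]], g_without[["cf.l1.W"]], tolerance = 1e-12)
  # trunk gradients differ only by the additive context contribution, so
  # the CF-only component is recoverable: check a shared tensor changes
  expect_false(isTRUE(all.equal(g_with[["mix.l1.W"]],
                                g_without[["mix.l1.W"]])))
})
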