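test_that("confusion counts exactly and drops UNKNOWN pairwise", {
  h <- new_hypnogram(rep(c("W", "N2"), 5))
  cm <- confusion(h, h)
  expect_identical(sum(diag(cm)), 10L)
  expect_identical(sum(cm) - sum(diag(cm)), 0L)

  cm2 <- confusion(c("N1", "N1"), c("N2", "N2"))
  expect_identical(unname(cm2["N1", "N2"]), 2L)
  expect_identical(sum(cm2), 2L)

  cm3 <- confusion(c("W", "UNKNOWN", "N2"), c("W", "W", "UNKNOWN"))
  expect_identical(sum(cm3), 1L)

  expect_error(confusion(c("W", "W"), "W"), "length mismatch")

  set.seed(11)
  t200 <- sample(STAGES, 200, TRUE)
  p200 <- sample(STAGES, 200, TRUE)
  cm4 <- confusion(t200, p200)
  tally <- matrix(0L, 5, 5)
  for (i in 1:200)
    tally[match(t200[i], STAGES), match(p200[i], STAGES)] <-
      tally[match(t200[i], STAGES), match(p200[i], STAGES)] + 1L
  expect_identical(unclass(cm4), structure(tally,
    dimnames = list(true = STAGES, pred = STAGES)))
  rn <- row_normalize(cm4)
  expect_true(all(abs(rowSums(rn) - 1) < 1e-12))
})

test_that("perfect and binary-embedded confusion matrices give known values", {
  perfect <- confusion(rep(STAGES, 4), rep(STAGES, 4))
  expect_equal(mcc(perfect), 1)
  expect_equal(f1_macro(perfect), 1)
  expect_equal(accuracy(perfect), 1)
  expect_equal(kappa_score(perfect), 1)

  # 2-class MCC closed form: TP=40, TN=40, FP=10, FN=10 -> 0.6
  cm <- matrix(0L, 5, 5, dimnames = list(true = STAGES, pred = STAGES))
  cm["W", "W"] <- 40L; cm["N2", "N2"] <- 40L
  cm["N2", "W"] <- 10L; cm["W", "N2"] <- 10L
  expect_equal(mcc(structure(cm, class = "confusion_matrix")), 0.6)
})

test_that("all metrics match independent oracles on 100 random matrices", {
  for (seed in 1:100) {
    cm <- random_cm(seed)
    if (sum(cm) == 0) next
    expect_equal(mcc(cm), oracle_mcc(unclass(cm)), tolerance = 1e-10)
    expect_equal(suppressWarnings(f1_per_stage(cm)), oracle_f1(unclass(cm)),
                 tolerance = 1e-10)
    expect_equal(accuracy(cm), oracle_accuracy(unclass(cm)),
                 tolerance = 1e-10)
    expect_equal(kappa_score(cm), oracle_kappa(unclass(cm)),
                 tolerance = 1e-10)
    expect_equal(suppressWarnings(f1_macro(cm)),
                 mean(oracle_f1(unclass(cm))), tolerance = 1e-10)
  }
})

test_that("absent stages warn and count as F1 = 0", {
  cm <- confusion(rep("W", 10), rep("W", 10))
  expect_warning(f1 <- f1_per_stage(cm), "absent")
  expect_identical(unname(f1[c("N1", "N2", "N3", "REM")]), rep(0, 4))
  expect_equal(f1_macro(cm, drop_absent = TRUE), 1)
  expect_error(mcc(matrix(0, 5, 5)), "empty")
})

test_that("stage proportions sum to one and aggregate linearly", {
  p <- stage_proportions(new_hypnogram(c("W", "W", "N2", "N2")))
  expect_equal(unname(p), c(0.5, 0, 0.5, 0, 0))

  set.seed(12)
  a <- new_hypnogram(sample(STAGES, 30, TRUE))
  b <- new_hypnogram(sample(STAGES, 70, TRUE))
  joint <- new_hypnogram(c(unclass(a), unclass(b)))
  expect_equal(stage_proportions(joint),
               0.3 * stage_proportions(a) + 0.7 * stage_proportions(b))

  expect_equal(unname(stage_proportions(new_hypnogram(rep("N3", 5)))["N3"]), 1)
  expect_error(stage_proportions(new_hypnogram(rep("UNKNOWN", 3))),
               "no scored")
})

test_that("transition rate follows the (length - 1) convention", {
  expect_equal(transition_rate(new_hypnogram(c("W", "W", "N1", "N1", "N2"))),
               0.5)
  expect_equal(transition_rate(new_hypnogram(rep("N2", 50))), 0)
  expect_equal(transition_rate(new_hypnogram(rep(c("W", "N1"), 10))), 1)
  expect_equal(transition_rate(new_hypnogram(c("W", "W", "N1", "N1")),
                               denominator = "length"), 0.25)
  # UNKNOWN-adjacent pairs are excluded from both counts
  expect_equal(transition_rate(new_hypnogram(c("W", "UNKNOWN", "W", "N1"))),
               1 / 1)
  expect_error(transition_rate(new_hypnogram("W")), "too short")
})

test_that("light-sleep merge behaves and commutes with confusion", {
  t5 <- c("N1", "N2", "W", "REM", "N3", "N1")
  p5 <- c("N2", "N1", "W", "REM", "N3", "W")
  cm5 <- confusion(t5, p5)
  # N1 vs N2 counted correct after merge
  cm4a <- merge_light_sleep(cm5)
  expect_identical(unname(cm4a["LIGHT", "LIGHT"]), 2L)
  expect_gte(accuracy(cm4a), accuracy(cm5))
  # commutativity: merge-then-confuse equals confuse-then-merge
  cm4b <- confusion_light(merge_light_sleep(t5), merge_light_sleep(p5))
  expect_identical(unclass(cm4a), unclass(cm4b))
  expect_error(merge_light_sleep(cm4a), "already")
  expect_error(merge_light_sleep(merge_light_sleep(t5)), "already")

  # merging can only remove errors: property over random pairs
  set.seed(13)
  for (i in 1:20) {
    t <- sample(STAGES, 100, TRUE)
    p <- sample(STAGES, 100, TRUE)
    expect_lte(accuracy(confusion(t, p)),
               accuracy(merge_light_sleep(confusion(t, p))))
  }
})

test_that("metrics_report aggregates with medians", {
  set.seed(14)
  tl <- lapply(1:5, function(i) new_hypnogram(sample(STAGES, 60, TRUE)))
  pl <- lapply(tl, function(h) {
    s <- as.character(h)
    flip <- sample(60, 10)
    s[flip] <- sample(STAGES, 10, TRUE)
    new_hypnogram(s)
  })
  rep <- metrics_report(tl, pl)
  expect_identical(nrow(rep$per_psg), 5L)
  expect_equal(unname(rep$median["accuracy"]),
               median(rep$per_psg$accuracy))
  expect_true(all(rep$per_psg$accuracy >= 0 & rep$per_psg$accuracy <= 1))
  expect_true(all(rep$per_psg$mcc >= -1 & rep$per_psg$mcc <= 1))
})
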