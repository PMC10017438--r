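# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

ns <- asNamespace("somnostage")

# tiny architecture for gradient checks and fast forward passes
tiny_model_config <- function(dropout_p = 0) {
  model_config(widths = c(3L, 4L), strides = c(4L, 4L), kernel_stem = 5L,
               kernel = 3L, eeg_blocks = 1L, eog_blocks = 1L, pool_len = 2L,
               mix_len = 6L, input_len = 64L, dropout_p = dropout_p)
}

tiny_model <- function(seed = 42, dropout_p = 0) {
  set.seed(seed)
  init_model(tiny_model_config(dropout_p))
}

# small preprocessed synthetic data set, memoized across tests in a session
.fixture_env <- new.env()

fixture_psgs <- function(n_nights = 4, epochs_per_night = 40, seed = 301) {
  key <- paste0("psgs_", n_nights, "_", epochs_per_night, "_", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- synth_psg_set(n_nights, epochs_per_night,
                                         sfreq = 100, seed = seed)
  .fixture_env[[key]]
}

## ---- independent permutation enumerator (cartesian product + filter) ----

brute_force_perms <- function(eeg_channels, has_eog, flips) {
  signs <- if (flips) c(1, -1) else 1
  out <- character()
  for (eeg in c(NA, eeg_channels)) {
    for (eog in c(FALSE, TRUE)) {
      if (is.na(eeg) && !eog) next
      if (eog && !has_eog) next
      es <- if (!is.na(eeg)) signs else 1
      os <- if (eog) signs else 1
      for (fe in es) for (fo in os) {
        lbl <- c(if (!is.na(eeg)) paste0(if (fe < 0) "-" else "", eeg),
                 if (eog) paste0(if (fo < 0) "-" else "", "HEOG"))
        out <- c(out, paste(lbl, collapse = "+"))
      }
    }
  }
  unique(out)
}

## ---- independent metric oracles (different algebra / expanded labels) ---

cm_to_labels <- function(cm) {
  true <- pred <- character()
  for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm))) {
    k <- cm[i, j]
    if (k > 0) {
      true <- c(true, rep(rownames(cm)[i], k))
      pred <- c(pred, rep(colnames(cm)[j], k))
    }
  }
  list(true = true, pred = pred)
}

# Gorodkin MCC via the explicit triple-sum form (different computational
# path from the marginal-sum form used by the implementation)
oracle_mcc <- function(cm) {
  K <- nrow(cm)
  num <- 0
  for (k in 1:K) for (l in 1:K) for (m in 1:K)
    num <- num + cm[k, k] * cm[l, m] - cm[k, l] * cm[m, k]
  d1 <- 0; d2 <- 0
  for (k in 1:K) {
    rk <- sum(cm[k, ])
    ck <- sum(cm[, k])
    d1 <- d1 + rk * sum(cm[-k, ])
    d2 <- d2 + ck * sum(cm[, -k])
  }
  if (d1 == 0 || d2 == 0) return(0)
  num / (sqrt(d1) * sqrt(d2))
}

oracle_f1 <- function(cm) {
  lab <- cm_to_labels(cm)
  vapply(rownames(cm), function(s) {
    tp <- sum(lab$true == s & lab$pred == s)
    fp <- sum(lab$true != s & lab$pred == s)
    fn <- sum(lab$true == s & lab$pred != s)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

oracle_accuracy <- function(cm) {
  lab <- cm_to_labels(cm)
  mean(lab$true == lab$pred)
}

oracle_kappa <- function(cm) {
  lab <- cm_to_labels(cm)
  n <- length(lab$true)
  po <- mean(lab$true == lab$pred)
  pe <- 0
  for (s in rownames(cm))
    pe <- pe + mean(lab$true == s) * mean(lab$pred == s)
  (po - pe) / (1 - pe)
}

random_cm <- function(seed) {
  set.seed(seed)
  m <- matrix(rpois(25, lambda = sample(1:40, 1)), 5, 5,
              dimnames = list(true = STAGES, pred = STAGES))
  # occasionally zero out a stage entirely to hit the absent-stage path
  if (seed %% 10 == 0) m[2, ] <- m[, 2] <- 0L
  structure(m, class = "confusion_matrix")
}

# scalar-loop weighted cross entropy oracle
oracle_wce <- function(logp, targets, w) {
  num <- 0; den <- 0
  for (i in seq_along(targets)) {
    wi <- w[[targets[i]]]
    num <- num + wi * (-logp[match(targets[i], STAGES), i])
    den <- den + wi
  }
  num / den
}

random_logp <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(rnorm(5 * n), 5, n)
  ns$log_softmax(z)
}
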