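# Inference modes:
#   bidirectional  full-sequence GRU in both directions (offline scoring)
#   forward        forward GRU direction only, hidden carried in time
#                  (real-time/BCI equivalent; exactly reproducible epoch by
#                  epoch with stream_step())
#   context_free   fully-connected head, single epochs, no context
# Certainty of an inference is the cross-entropy of the log-softmax output
# against its own argmax stage, i.e. -log p(inferred stage): 0 is maximal
# certainty.  The permutation consensus adopts, per epoch, the permutation
# with the smallest certainty value.

INFER_MODES <- c("bidirectional", "forward", "context_free")

argmax_stage <- function(logp) {
  # ties break toward the lower stage index (W < N1 < N2 < N3 < REM)
  apply(logp, 2, which.max)
}

new_inference_result <- function(logp, perm_label, mode) {
  idx <- argmax_stage(logp)
  structure(list(hypnogram = new_hypnogram(STAGES[idx]),
                 log_probs = logp,
                 certainties = -logp[cbind(idx, seq_along(idx))],
                 permutation = perm_label, mode = mode),
            class = "inference_result")
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("<inference_result> %d epochs, mode=%s, view=%s\n",
              length(x$hypnogram), x$mode, x$permutation))
  invisible(x)
}

# Evaluation-mode trunk over all epochs, chunked to bound cache memory.
trunk_eval <- function(model, inp, chunk = 64L) {
  n <- dim(if (!is.null(inp$eeg)) inp$eeg else inp$eog)[3]
  mix <- matrix(0, model$cfg$mix_len, n)
  for (a in seq(1L, n, by = chunk)) {
    b <- min(a + chunk - 1L, n)
    tr <- trunk_fwd(model, subset_epochs(inp$eeg, a:b),
                    subset_epochs(inp$eog, a:b), training = FALSE)
    mix[, a:b] <- tr$y
  }
  mix
}

check_fingerprint <- function(model, epochs) {
  if (!is.null(epochs$fingerprint) &&
      !identical(epochs$fingerprint, model$fingerprint))
    stop("preprocessing fingerprint mismatch: model expects ",
         model$fingerprint, " but data carry ", epochs$fingerprint)
}

#' Infer sleep stages for one permutation
#'
#' @param model a `somnostage_model`.
#' @param epochs an `epoched_signals` object (preprocessing-compatible with
#'   the model).
#' @param perm a [signal_permutation()].
#' @param mode `"bidirectional"`, `"forward"` or `"context_free"`.
#' @return An `inference_result`: per-epoch hypnogram, `5 x n` log
#'   probabilities, certainties, permutation label and mode.
#' @export
infer <- function(model, epochs, perm, mode = INFER_MODES) {
  mode <- match.arg(mode)
  check_fingerprint(model, epochs)
  if (n_epochs(epochs) < 1) stop("no epochs to infer")
  inp <- apply_permutation(epochs, perm)
  mix <- trunk_eval(model, inp)
  logp <- switch(mode,
    context_free = cf_fwd(model, mix, training = FALSE)$logp,
    forward = ctx_fwd_seq(model, mix, h0f = matrix(0, model$cfg$gru_hidden, 1),
                          training = FALSE, bidir = FALSE)$logp,
    bidirectional = ctx_fwd_seq(model, mix,
                                h0f = matrix(0, model$cfg$gru_hidden, 1),
                                h0b = matrix(0, model$cfg$gru_hidden, 1),
                                training = FALSE, bidir = TRUE)$logp)
  new_inference_result(logp, format(perm), mode)
}

#' Streaming single-epoch inference
#'
#' Real-time equivalent of forward-mode [infer()]: processes one new 30-s
#' epoch given the hidden state carried from the previous call.  `T`
#' sequential calls starting from `hidden = NULL` reproduce forward-mode
#' inference over the same `T` epochs.
#'
#' @param model a `somnostage_model`.
#' @param epoch_data list with `eeg` and/or `eog`: one preprocessed
#'   2,560-sample epoch per present signal.
#' @param hidden state from the previous call, or `NULL` (zero state).
#' @return List with `stage`, `log_probs`, `certainty`, updated `hidden`,
#'   and the measured per-step `latency_s`.
#' @export
stream_step <- function(model, epoch_data, hidden = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(epoch_data$eeg) && is.null(epoch_data$eog))
    stop("epoch_data must contain at least one of eeg/eog")
  shape <- function(v) if (is.null(v)) NULL else
    as_epoch_array(as.numeric(v), model$cfg$input_len)
  inp <- list(eeg = shape(epoch_data$eeg), eog = shape(epoch_data$eog))
  mix <- trunk_eval(model, inp)
  if (is.null(hidden)) hidden <- zero_hidden(model)
  out <- head_context(model, mix[, 1], hidden)
  idx <- which.max(out$log_probs)
  list(stage = STAGES[idx], log_probs = out$log_probs,
       certainty = -out$log_probs[[idx]], hidden = out$hidden,
       latency_s = proc.time()[["elapsed"]] - t0)
}

#' Certainty of a stage distribution
#'
#' The cross-entropy of the log-softmax output against the inferred
#' (argmax) stage: `-log p(argmax)`.  0 means maximal certainty; larger
#' values mean less certain.
#'
#' @param dist length-5 log-probability vector, or a `5 x n` matrix.
#' @return Non-negative scalar (or vector of `n`).
#' @export
certainty <- function(dist) {
  m <- as.matrix(dist)
  if (!all(is.finite(m))) stop("non-finite log-probabilities")
  idx <- argmax_stage(m)
  unname(-m[cbind(idx, seq_along(idx))])
}

#' Certainty-based permutation consensus
#'
#' Combines inference results from multiple signal permutations by
#' adopting, independently for every epoch, the stage (and distribution)
#' of the permutation with the highest certainty, i.e. the smallest
#' cross-entropy against its own inferred stage.
#'
#' @param results list of `inference_result`s over the same epochs and mode.
#' @return An `inference_result` with `permutation = "CONSENSUS"`.
#' @export
consensus <- function(results) {
  if (!length(results)) stop("no inference results to combine")
  n <- length(results[[1]]$hypnogram)
  mode <- results[[1]]$mode
  for (r in results) {
    if (length(r$hypnogram) != n)
      stop("inference results have mismatched epoch counts")
    if (!identical(r$mode, mode))
      stop("inference results have mismatched modes")
  }
  cert <- do.call(rbind, lapply(results, `[[`, "certainties"))
  pick <- apply(cert, 2, which.min)
  logp <- matrix(0, 5, n)
  for (i in seq_len(n)) logp[, i] <- results[[pick[i]]]$log_probs[, i]
  out <- new_inference_result(logp, "CONSENSUS", mode)
  out$source_permutation <- vapply(results, `[[`, character(1), "permutation")[pick]
  out
}

#' Score a PSG with the permutation consensus
#'
#' Convenience wrapper: enumerates the montage's permutations, infers each,
#' and combines them with [consensus()].
#'
#' @param model a `somnostage_model`.
#' @param epochs an `epoched_signals` object.
#' @param mode inference mode.
#' @param polarity_flips include polarity-flipped views.
#' @export
infer_consensus <- function(model, epochs, mode = "bidirectional",
                            polarity_flips = TRUE) {
  perms <- perms_for_epochs(epochs, polarity_flips)
  consensus(lapply(perms, function(p) infer(model, epochs, p, mode)))
}

#' Extract latent vectors
#'
#' Returns, for every epoch, the three aligned latent representations: the
#' mixer output, the penultimate layer of the context-free head, and the
#' penultimate (projection) vector of the context head — all of length
#' `mix_len` (512 in the default architecture), so they can be compared
#' directly (e.g. with UMAP).
#'
#' @param model a `somnostage_model`.
#' @param epochs an `epoched_signals` object.
#' @param perm a [signal_permutation()].
#' @return List of three `mix_len x n` matrices: `mixer`,
#'   `cf_penultimate`, `ctx_penultimate`.
#' @export
extract_latents <- function(model, epochs, perm) {
  check_fingerprint(model, epochs)
  inp <- apply_permutation(epochs, perm)
  mix <- trunk_eval(model, inp)
  cf <- cf_fwd(model, mix, training = FALSE)
  cx <- ctx_fwd_seq(model, mix, h0f = matrix(0, model$cfg$gru_hidden, 1),
                    h0b = matrix(0, model$cfg$gru_hidden, 1),
                    training = FALSE, bidir = TRUE)
  list(mixer = mix, cf_penultimate = cf$penultimate,
       ctx_penultimate = cx$penultimate)
}
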