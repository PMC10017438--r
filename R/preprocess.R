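# Preprocessing chain, applied in fixed order:
#   band-pass FIR -> per-channel z-score -> HEOG derivation -> resample/epoch
# The chain is deterministic; its parameters are captured in a
# `preprocess_config` whose fingerprint is stored inside trained models so
# that inference can refuse incompatibly prepared input.

#' Preprocessing configuration
#'
#' @param l_freq,h_freq band-pass edges in Hz.  The defaults (0.3 and 30 Hz)
#'   retain all sleep-relevant rhythms (slow oscillations through sleep
#'   spindles) and exclude line noise.
#' @param target_samples_per_epoch samples per 30-s epoch after resampling.
#'   The default 2,560 defines the network input length; the implied target
#'   rate is exactly `2560/30` Hz (85.33 Hz rounded).
#' @param epoch_len_s scoring epoch length, fixed at 30 s.
#' @param l_trans,h_trans FIR transition bandwidths in Hz; `NULL` uses the
#'   usual M/EEG heuristic (`min(max(f/4, 2), edge distance)`), which gives
#'   0.3 Hz and 7.5 Hz for the default band.
#' @param filter set `FALSE` to skip the band-pass for pre-filtered input.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(l_freq = 0.3, h_freq = 30,
                              target_samples_per_epoch = 2560L,
                              epoch_len_s = 30, l_trans = NULL,
                              h_trans = NULL, filter = TRUE) {
  stopifnot(l_freq > 0, l_freq < h_freq, target_samples_per_epoch >= 1,
            epoch_len_s == 30)
  structure(list(l_freq = l_freq, h_freq = h_freq,
                 target_samples_per_epoch = as.integer(target_samples_per_epoch),
                 epoch_len_s = epoch_len_s, l_trans = l_trans,
                 h_trans = h_trans, filter = isTRUE(filter)),
            class = "preprocess_config")
}

preprocess_fingerprint <- function(cfg) {
  paste0("bp", cfg$l_freq, "-", cfg$h_freq, ";spe",
         cfg$target_samples_per_epoch, ";el", cfg$epoch_len_s,
         ";filt", as.integer(cfg$filter))
}

#' Zero-phase band-pass filter a recording
#'
#' One-pass, zero-phase (group-delay compensated) Hamming windowed-sinc FIR
#' band-pass applied per channel.  Removes DC; preserves length.
#'
#' @param rec a [new_recording()].
#' @param cfg a [preprocess_config()].
#' @return Filtered recording.
#' @export
bandpass_filter <- function(rec, cfg = preprocess_config()) {
  if (rec$sfreq <= 2 * cfg$h_freq)
    stop("sampling rate ", rec$sfreq, " Hz too low for a ", cfg$h_freq,
         " Hz upper edge")
  h <- design_bandpass_fir(rec$sfreq, cfg$l_freq, cfg$h_freq,
                           cfg$l_trans, cfg$h_trans)
  for (i in seq_len(nrow(rec$signals)))
    rec$signals[i, ] <- fir_filt_zerophase(rec$signals[i, ], h)
  rec$meta$filtered <- c(cfg$l_freq, cfg$h_freq)
  rec
}

#' Z-transform each channel over the whole recording
#'
#' Per-channel, per-recording standardization to mean 0, population standard
#' deviation 1.
#'
#' @param rec a [new_recording()].
#' @return Standardized recording.
#' @export
zscore_per_channel <- function(rec) {
  for (i in seq_len(nrow(rec$signals))) {
    x <- rec$signals[i, ]
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    if (s < 1e-12)
      stop("zero-variance channel: ", rec$channel_names[i])
    rec$signals[i, ] <- (x - m) / s
  }
  rec$meta$zscored <- TRUE
  rec
}

#' Derive the horizontal EOG channel
#'
#' Subtracts the right EOG channel from the left to form a single HEOG
#' channel, which replaces the monopolar pair in the network-facing channel
#' set.  The derived channel is re-standardized so all network inputs share
#' unit scale.
#'
#' @param rec a [new_recording()] containing roles `EOG_L` and `EOG_R`.
#' @return Recording with channel `HEOG` appended and the EOG pair removed.
#' @export
derive_heog <- function(rec) {
  l <- channels_by_role(rec, "EOG_L")
  r <- channels_by_role(rec, "EOG_R")
  if (length(l) != 1 || length(r) != 1)
    stop("derive_heog requires exactly one EOG_L and one EOG_R channel")
  heog <- rec$signals[l, ] - rec$signals[r, ]
  m <- mean(heog)
  s <- sqrt(mean((heog - m)^2))
  if (s > 1e-12) heog <- (heog - m) / s
  keep <- !(rec$channel_names %in% c(l, r))
  signals <- rbind(rec$signals[keep, , drop = FALSE], HEOG = heog)
  names <- c(rec$channel_names[keep], "HEOG")
  roles <- c(rec$channel_roles[keep], HEOG = "HEOG")
  new_recording(signals, rec$sfreq, names, roles, rec$meta)
}

#' Epoched, resampled network input
#'
#' Resamples all channels to exactly `target_samples_per_epoch` samples per
#' 30-s epoch (polyphase, anti-aliased), slices the recording into epochs,
#' discards a trailing partial epoch, and aligns the hypnogram to the
#' resulting epoch count.
#'
#' @param rec a [new_recording()].
#' @param hyp optional [new_hypnogram()]; truncated/aligned to the epoch
#'   count.
#' @param cfg a [preprocess_config()].
#' @return A list with `epochs` (class `epoched_signals`: array channels x
#'   samples x epochs plus role metadata) and `hypnogram` (or `NULL`).
#' @export
epoch_and_resample <- function(rec, hyp = NULL, cfg = preprocess_config()) {
  spe <- cfg$target_samples_per_epoch
  target_rate <- spe / cfg$epoch_len_s
  sig <- lapply(seq_len(nrow(rec$signals)), function(i)
    resample_poly(rec$signals[i, ], target_rate, rec$sfreq))
  n_out <- min(lengths(sig))
  n_ep <- n_out %/% spe
  if (n_ep < 1) stop("recording shorter than one 30-s epoch after resampling")
  if (!is.null(hyp)) n_ep <- min(n_ep, length(hyp))
  if (n_ep < 1) stop("no usable epochs (empty hypnogram?)")
  C <- nrow(rec$signals)
  data <- array(0, dim = c(C, spe, n_ep))
  for (i in seq_len(C))
    data[i, , ] <- sig[[i]][seq_len(n_ep * spe)]
  epochs <- structure(list(data = data, channel_names = rec$channel_names,
                           channel_roles = rec$channel_roles,
                           fingerprint = preprocess_fingerprint(cfg),
                           epoch_origin = 1L),
                      class = "epoched_signals")
  if (!is.null(hyp)) hyp <- hyp[seq_len(n_ep)]
  list(epochs = epochs, hypnogram = hyp)
}

#' @export
print.epoched_signals <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_signals> %d epoch(s) x %d channel(s) x %d samples\n",
              d[3], d[1], d[2]))
  invisible(x)
}

n_epochs <- function(ep) dim(ep$data)[3]

#' Full preprocessing chain
#'
#' Applies, in order: band-pass filter (unless disabled), per-channel
#' z-scoring, HEOG derivation (when an EOG pair is present), and
#' resampling/epoching to 2,560 samples per epoch.
#'
#' @param rec a [new_recording()].
#' @param hyp optional [new_hypnogram()].
#' @param cfg a [preprocess_config()].
#' @return As [epoch_and_resample()].
#' @export
preprocess_psg <- function(rec, hyp = NULL, cfg = preprocess_config()) {
  if (cfg$filter) rec <- bandpass_filter(rec, cfg)
  rec <- zscore_per_channel(rec)
  has_eog <- length(channels_by_role(rec, "EOG_L")) == 1 &&
             length(channels_by_role(rec, "EOG_R")) == 1
  if (has_eog) rec <- derive_heog(rec)
  epoch_and_resample(rec, hyp, cfg)
}
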