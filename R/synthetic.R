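# Synthetic PSG generator.  Produces hypnograms from a stage-transition
# Markov chain and per-epoch signals with stage-dependent spectral
# signatures mirroring the AASM scoring cues: occipital alpha in wake,
# theta in N1, spindles and K-complexes in N2, high-amplitude slow
# oscillations in N3, and large slow anti-phase EOG deflections in REM.
# Signatures are deliberately stronger than real physiology so that a
# desk-scale classifier can learn them; amplitudes are exposed so the
# difficulty can be raised.

#' Stage-transition model
#'
#' Markov transition matrix over the five stages with a dwell-heavy
#' diagonal.  By default N3 is reachable only from N2 (and itself),
#' mirroring observed sleep architecture.
#'
#' @param P 5 x 5 transition matrix (rows = from, in stage order); rows
#'   must sum to 1.
#' @param init initial stage distribution (defaults to starting awake).
#' @export
transition_model <- function(P = NULL, init = c(1, 0, 0, 0, 0)) {
  if (is.null(P)) {
    P <- rbind(
      W   = c(0.88, 0.12, 0.00, 0.00, 0.00),
      N1  = c(0.05, 0.60, 0.35, 0.00, 0.00),
      N2  = c(0.00, 0.05, 0.82, 0.08, 0.05),
      N3  = c(0.00, 0.00, 0.15, 0.85, 0.00),
      REM = c(0.03, 0.00, 0.07, 0.00, 0.90))
  }
  P <- as.matrix(P)
  if (!all(dim(P) == c(5, 5)) || any(P < 0) ||
      any(abs(rowSums(P) - 1) > 1e-8))
    stop("transition matrix must be 5x5 with nonnegative rows summing to 1")
  if (length(init) != 5 || any(init < 0) || abs(sum(init) - 1) > 1e-8)
    stop("invalid initial distribution")
  dimnames(P) <- list(STAGES, STAGES)
  structure(list(P = P, init = init), class = "transition_model")
}

#' Sample a hypnogram from a transition model
#'
#' @param n_ep number of 30-s epochs.
#' @param tm a [transition_model()].
#' @param seed optional RNG seed for reproducibility.
#' @export
generate_hypnogram <- function(n_ep, tm = transition_model(), seed = NULL) {
  stopifnot(inherits(tm, "transition_model"), n_ep >= 1)
  if (!is.null(seed)) set.seed(seed)
  s <- integer(n_ep)
  s[1] <- sample.int(5, 1, prob = tm$init)
  for (i in seq_len(n_ep - 1))
    s[i + 1] <- sample.int(5, 1, prob = tm$P[s[i], ])
  new_hypnogram(STAGES[s])
}

#' Stage signature model
#'
#' Amplitudes (arbitrary microvolt-like units) and bands (Hz) of the
#' per-stage spectral recipes.  All bands must lie below the Nyquist
#' frequency of the generated recording.
#'
#' @param ... overrides of the default fields (see source for the list).
#' @export
stage_signature_model <- function(...) {
  sig <- list(
    noise_sd = 10,          # broadband EEG background
    eog_noise_sd = 8,
    alpha_band = c(8, 12),  alpha_amp = 22,     # W
    theta_band = c(4, 7),   theta_amp = 18,     # N1 (and N2 background)
    n1_alpha_amp = 6,                           # attenuated alpha residue
    n2_bg_amp = 10,
    spindle_freq = 13.5,    spindle_amp = 28,   # N2 bursts
    spindles_per_epoch = 3, spindle_dur = 1.0,
    kcomplex_amp = 60,      kcomplex_prob = 0.8,
    so_band = c(0.6, 1.2),  so_amp = 70,        # N3 slow oscillations
    rem_band = c(3, 8),     rem_amp = 10,       # REM mixed-frequency EEG
    sem_band = c(0.3, 0.8), sem_amp = 80,       # REM slow eye movements
    n1_roll_band = c(0.2, 0.5), n1_roll_amp = 30,
    w_sacc_band = c(1, 3),  w_sacc_amp = 20)
  over <- list(...)
  bad <- setdiff(names(over), names(sig))
  if (length(bad)) stop("unknown signature field(s): ", paste(bad, collapse = ", "))
  sig[names(over)] <- over
  stopifnot(all(unlist(sig[grep("amp|sd", names(sig))]) > 0))
  structure(sig, class = "stage_signature_model")
}

# band-limited Gaussian noise scaled to RMS `amp`
narrowband <- function(ns, sfreq, band, amp) {
  x <- rnorm(ns)
  f <- fft(x)
  freqs <- (seq_len(ns) - 1) / ns * sfreq
  freqs <- pmin(freqs, sfreq - freqs)         # two-sided
  f[freqs < band[1] | freqs > band[2]] <- 0
  y <- Re(fft(f, inverse = TRUE)) / ns
  r <- sqrt(mean(y^2))
  if (r < 1e-12) return(numeric(ns))
  y * amp / r
}

spindle_burst <- function(ns, sfreq, sig) {
  y <- numeric(ns)
  k <- rpois(1, sig$spindles_per_epoch)
  dur <- round(sig$spindle_dur * sfreq)
  if (k == 0 || dur >= ns) return(y)
  for (i in seq_len(k)) {
    a <- sample.int(ns - dur, 1)
    t <- seq_len(dur) / sfreq
    env <- sin(pi * seq_len(dur) / dur)^2     # Hann-like envelope
    y[a:(a + dur - 1)] <- y[a:(a + dur - 1)] +
      sig$spindle_amp * env * sin(2 * pi * sig$spindle_freq * t + runif(1, 0, 2 * pi))
  }
  y
}

kcomplex <- function(ns, sfreq, sig) {
  y <- numeric(ns)
  if (runif(1) > sig$kcomplex_prob) return(y)
  dur <- round(1.2 * sfreq)
  if (dur >= ns) return(y)
  a <- sample.int(ns - dur, 1)
  t <- seq_len(dur) / dur
  # biphasic: sharp negative trough then slower positive rebound
  y[a:(a + dur - 1)] <- sig$kcomplex_amp * (-sin(2 * pi * t) * sin(pi * t))
  y
}

# one epoch of EEG for a given stage
eeg_epoch_signal <- function(stage, ns, sfreq, sig) {
  base <- rnorm(ns, sd = sig$noise_sd)
  base + switch(stage,
    W = narrowband(ns, sfreq, sig$alpha_band, sig$alpha_amp),
    N1 = narrowband(ns, sfreq, sig$theta_band,
                    sig$theta_amp * runif(1, 0.6, 1.4)) +
         narrowband(ns, sfreq, sig$alpha_band, sig$n1_alpha_amp),
    N2 = narrowband(ns, sfreq, sig$theta_band, sig$n2_bg_amp) +
         spindle_burst(ns, sfreq, sig) + kcomplex(ns, sfreq, sig),
    N3 = narrowband(ns, sfreq, sig$so_band, sig$so_amp),
    REM = narrowband(ns, sfreq, sig$rem_band, sig$rem_amp))
}

# anti-phase component of the EOG pair for one epoch (L gets +, R gets -)
eog_epoch_signal <- function(stage, ns, sfreq, sig) {
  switch(stage,
    W = narrowband(ns, sfreq, sig$w_sacc_band, sig$w_sacc_amp),
    N1 = narrowband(ns, sfreq, sig$n1_roll_band, sig$n1_roll_amp),
    REM = narrowband(ns, sfreq, sig$sem_band, sig$sem_amp),
    numeric(ns))
}

#' Generate a synthetic PSG recording for a hypnogram
#'
#' Synthesizes per-epoch signals according to the stage signature recipes.
#' EEG channels get independent noise realizations of the same recipe; the
#' EOG pair carries slow deflections that are anti-phase between left and
#' right (so the HEOG difference amplifies them) plus an in-phase EEG bleed
#' (which HEOG cancels).
#'
#' @param hyp a [new_hypnogram()] (must contain no `UNKNOWN` epochs).
#' @param montage list with `eeg` (character vector of labels) and `eog`
#'   (length-2 vector `c(left, right)` or `NULL`).
#' @param sfreq sampling rate in Hz (>= 100 so all bands fit).
#' @param sig a [stage_signature_model()].
#' @param seed optional RNG seed.
#' @return A [new_recording()].
#' @export
generate_psg <- function(hyp, montage = list(eeg = c("C3", "C4"),
                                             eog = c("EOGL", "EOGR")),
                         sfreq = 100, sig = stage_signature_model(),
                         seed = NULL) {
  stopifnot(is_hypnogram(hyp), sfreq >= 100)
  if (any(as.character(hyp) == "UNKNOWN"))
    stop("generate_psg requires a fully scored hypnogram")
  if (!is.null(seed)) set.seed(seed)
  ns <- round(30 * sfreq)
  n_ep <- length(hyp)
  labels <- c(montage$eeg, montage$eog)
  roles <- setNames(c(rep("EEG", length(montage$eeg)),
                      if (length(montage$eog)) c("EOG_L", "EOG_R")),
                    labels)
  x <- matrix(0, nrow = length(labels), ncol = ns * n_ep,
              dimnames = list(labels, NULL))
  for (i in seq_len(n_ep)) {
    st <- as.character(hyp)[i]
    cols <- (i - 1) * ns + seq_len(ns)
    for (ch in montage$eeg)
      x[ch, cols] <- eeg_epoch_signal(st, ns, sfreq, sig)
    if (length(montage$eog)) {
      anti <- eog_epoch_signal(st, ns, sfreq, sig)
      bleed <- 0.3 * eeg_epoch_signal(st, ns, sfreq, sig)
      x[montage$eog[1], cols] <- bleed + anti +
        rnorm(ns, sd = sig$eog_noise_sd)
      x[montage$eog[2], cols] <- bleed - anti +
        rnorm(ns, sd = sig$eog_noise_sd)
    }
  }
  new_recording(x, sfreq, labels, roles,
                meta = list(synthetic = TRUE, seed = seed))
}

#' Generate and preprocess a set of synthetic nights
#'
#' Convenience wrapper used by the tests and the CLI: samples a hypnogram
#' and recording per night and runs the preprocessing chain.
#'
#' @param n_nights number of nights.
#' @param epochs_per_night 30-s epochs per night.
#' @param sfreq sampling rate of the raw synthetic recordings.
#' @param seed base seed; night `i` uses `seed + i`.
#' @param montage as in [generate_psg()].
#' @param sig a [stage_signature_model()].
#' @param tm a [transition_model()].
#' @param pre_cfg a [preprocess_config()].
#' @return List of `list(epochs = <epoched_signals>, hypnogram =
#'   <hypnogram>)`, ready for [fit_model()] / [infer()].
#' @export
synth_psg_set <- function(n_nights, epochs_per_night = 100L, sfreq = 100,
                          seed = 1L,
                          montage = list(eeg = "C3",
                                         eog = c("EOGL", "EOGR")),
                          sig = stage_signature_model(),
                          tm = transition_model(),
                          pre_cfg = preprocess_config()) {
  lapply(seq_len(n_nights), function(i) {
    hyp <- generate_hypnogram(epochs_per_night, tm, seed = seed + i)
    rec <- generate_psg(hyp, montage, sfreq, sig)
    preprocess_psg(rec, hyp, pre_cfg)
  })
}
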