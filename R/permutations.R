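# Signal-permutation augmentation.  Each permutation is one "view" of a PSG
# presented to the network: an EEG channel alone, the HEOG channel alone, or
# both together, optionally with each present signal flipped in polarity
# (multiplied by -1).  Polarity flips emulate the reference-dependence of
# EEG and multiply the effective training set.

#' Construct a signal permutation
#'
#' @param eeg_channel EEG channel label, or `NA` for no EEG.
#' @param use_eog logical; include the HEOG channel?
#' @param eeg_flip,eog_flip polarity signs (+1 or -1); forced to +1 for an
#'   absent signal.
#' @return A list of class `signal_permutation`.
#' @export
signal_permutation <- function(eeg_channel = NA, use_eog = FALSE,
                               eeg_flip = 1, eog_flip = 1) {
  has_eeg <- !is.na(eeg_channel)
  if (!has_eeg && !use_eog)
    stop("a permutation must include at least one signal")
  stopifnot(eeg_flip %in% c(-1, 1), eog_flip %in% c(-1, 1))
  if (!has_eeg) eeg_flip <- 1
  if (!use_eog) eog_flip <- 1
  structure(list(eeg_channel = if (has_eeg) as.character(eeg_channel) else NA,
                 use_eog = isTRUE(use_eog),
                 eeg_flip = eeg_flip, eog_flip = eog_flip),
            class = "signal_permutation")
}

#' @export
format.signal_permutation <- function(x, ...) {
  parts <- character()
  if (!is.na(x$eeg_channel))
    parts <- c(parts, paste0(if (x$eeg_flip < 0) "-" else "", x$eeg_channel))
  if (x$use_eog)
    parts <- c(parts, paste0(if (x$eog_flip < 0) "-" else "", "HEOG"))
  paste(parts, collapse = "+")
}

#' @export
print.signal_permutation <- function(x, ...) {
  cat("<signal_permutation>", format(x), "\n")
  invisible(x)
}

#' Enumerate all signal permutations for a montage
#'
#' Lists every network input view: each EEG channel alone, the HEOG channel
#' alone (if present), and each EEG channel combined with HEOG.  With
#' polarity flips enabled, flips apply independently to each present signal,
#' so the count is `2E + 2*[eog] + 4E*[eog]` for `E` EEG channels (e.g. 14
#' views for two EEG channels plus EOG).  Ordering is deterministic: EEG-only
#' views in montage order, then EOG-only, then combined; +1 before -1.
#'
#' @param eeg_channels character vector of EEG channel labels (may be empty
#'   when `has_eog`).
#' @param has_eog logical; is an HEOG channel available?
#' @param polarity_flips logical; enumerate polarity-flipped views too?
#' @return List of [signal_permutation()] objects.
#' @export
enumerate_permutations <- function(eeg_channels, has_eog,
                                   polarity_flips = TRUE) {
  eeg_channels <- as.character(eeg_channels)
  if (!length(eeg_channels) && !has_eog)
    stop("montage has no signals: need at least one EEG channel or an EOG pair")
  flips <- if (polarity_flips) c(1, -1) else 1
  out <- list()
  for (ch in eeg_channels)
    for (f in flips)
      out[[length(out) + 1L]] <- signal_permutation(ch, FALSE, eeg_flip = f)
  if (has_eog)
    for (f in flips)
      out[[length(out) + 1L]] <- signal_permutation(NA, TRUE, eog_flip = f)
  if (has_eog)
    for (ch in eeg_channels)
      for (fe in flips)
        for (fo in flips)
          out[[length(out) + 1L]] <-
            signal_permutation(ch, TRUE, eeg_flip = fe, eog_flip = fo)
  out
}

#' Apply a permutation to epoched signals
#'
#' Extracts the permutation's channels from an `epoched_signals` object and
#' applies the polarity signs.  Returns the pair of network inputs.
#'
#' @param epochs an `epoched_signals` object (see [epoch_and_resample()]).
#' @param perm a [signal_permutation()].
#' @return List with `eeg` and `eog`: each either `NULL` or an array
#'   `1 x samples x epochs`.
#' @export
apply_permutation <- function(epochs, perm) {
  stopifnot(inherits(perm, "signal_permutation"))
  d <- dim(epochs$data)
  pick <- function(label, flip) {
    i <- match(label, epochs$channel_names)
    if (is.na(i)) stop("permutation references missing channel: ", label)
    array(flip * epochs$data[i, , ], dim = c(1, d[2], d[3]))
  }
  eeg <- if (!is.na(perm$eeg_channel)) pick(perm$eeg_channel, perm$eeg_flip)
  eog <- if (perm$use_eog) pick("HEOG", perm$eog_flip)
  list(eeg = eeg, eog = eog)
}
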