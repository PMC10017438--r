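#' Construct a PSG recording
#'
#' A `psg_recording` holds a multichannel continuous signal as a channels x
#' samples matrix with a single sampling rate, channel labels and channel
#' roles.  Roles tag each channel as `EEG`, `EOG_L`, `EOG_R`, `HEOG` or
#' `other`; the network consumes EEG channels and the derived HEOG channel.
#'
#' @param signals numeric matrix, channels x samples (microvolts or z-units).
#' @param sfreq sampling rate in Hz (scalar, > 0).
#' @param channel_names character vector of unique labels, one per row.
#' @param channel_roles named character vector mapping label to role; labels
#'   absent from the map default to `"other"`.
#' @param meta free-form list of provenance (filename, preprocessing flags).
#' @return An object of class `psg_recording`.
#' @export
new_recording <- function(signals, sfreq, channel_names,
                          channel_roles = NULL, meta = list()) {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1)
  stopifnot(is.numeric(signals), length(sfreq) == 1L, sfreq > 0)
  if (length(channel_names) != nrow(signals))
    stop("channel_names length must equal the number of signal rows")
  if (anyDuplicated(channel_names))
    stop("channel labels must be unique")
  roles <- setNames(rep("other", length(channel_names)), channel_names)
  if (!is.null(channel_roles)) {
    bad <- setdiff(channel_roles, c("EEG", "EOG_L", "EOG_R", "HEOG", "other"))
    if (length(bad)) stop("unknown channel role(s): ", paste(bad, collapse = ", "))
    known <- intersect(names(channel_roles), channel_names)
    roles[known] <- channel_roles[known]
  }
  rownames(signals) <- channel_names
  structure(list(signals = signals, sfreq = as.numeric(sfreq),
                 channel_names = channel_names, channel_roles = roles,
                 meta = meta),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %d channel(s) x %d samples @ %.4g Hz (%.1f s)\n",
              nrow(x$signals), ncol(x$signals), x$sfreq,
              ncol(x$signals) / x$sfreq))
  cat("  channels:",
      paste(sprintf("%s[%s]", x$channel_names, x$channel_roles), collapse = " "),
      "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$signals)

channels_by_role <- function(rec, role) {
  rec$channel_names[rec$channel_roles == role]
}

#' Construct a hypnogram
#'
#' A hypnogram is the sequence of sleep stage labels for a night, one label
#' per 30-s scoring epoch.  Stages are drawn from the AASM vocabulary
#' `W, N1, N2, N3, REM` plus `UNKNOWN` for unscored epochs.
#'
#' @param stages character vector of stage labels.
#' @param epoch_len_s epoch length in seconds; fixed at 30.
#' @return An object of class `hypnogram` (a character vector with
#'   attributes `epoch_len_s` and `vocabulary`).
#' @export
new_hypnogram <- function(stages, epoch_len_s = 30) {
  stages <- as.character(stages)
  if (epoch_len_s != 30) stop("epoch_len_s is fixed at 30 s")
  bad <- setdiff(unique(stages), STAGES_EXT)
  if (length(bad))
    stop("stage labels outside vocabulary: ", paste(bad, collapse = ", "))
  structure(stages, epoch_len_s = 30, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tb <- table(factor(unclass(x), levels = STAGES_EXT))
  cat(sprintf("<hypnogram> %d epochs (30 s): %s\n", length(x),
              paste(sprintf("%s=%d", names(tb), tb), collapse = " ")))
  invisible(x)
}

#' @export
`[.hypnogram` <- function(x, i) new_hypnogram(unclass(x)[i])

# integer codes 1..5 for scored stages, NA for UNKNOWN
stage_codes <- function(hyp) {
  match(unclass(hyp), STAGES)
}

is_hypnogram <- function(x) inherits(x, "hypnogram")
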