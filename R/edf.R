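# Minimal EDF/EDF+ continuous-recording support.  Only the subset of the
# format needed for PSG signal exchange is implemented: a fixed-duration
# data-record layout with 16-bit samples and per-channel physical scaling.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)  # left-justified, space padded
}

edf_num <- function(x, width) edf_pad(format(x, scientific = FALSE, trim = TRUE), width)

#' Read an EDF/EDF+ recording
#'
#' Parses the EDF header, extracts the requested channels and assigns the
#' roles given in `montage`.  Channels stored at different sampling rates are
#' resampled (polyphase, anti-aliased) up to the maximum rate among the
#' requested channels so the returned recording has a single `sfreq`.
#'
#' @param path path to an EDF file.
#' @param montage named character vector mapping channel label to role, e.g.
#'   `c(C3 = "EEG", EOGL = "EOG_L", EOGR = "EOG_R")`.  Only these channels
#'   are returned.
#' @return A [new_recording()] object.
#' @export
read_edf <- function(path, montage) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) rawToChar(readBin(con, "raw", n))
  version <- trimws(rd_str(8))
  rd_str(80); rd_str(80); rd_str(8); rd_str(8)
  header_bytes <- suppressWarnings(as.integer(trimws(rd_str(8))))
  rd_str(44)
  n_records <- suppressWarnings(as.integer(trimws(rd_str(8))))
  record_dur <- suppressWarnings(as.numeric(trimws(rd_str(8))))
  ns <- suppressWarnings(as.integer(trimws(rd_str(4))))
  if (is.na(ns) || is.na(n_records) || is.na(record_dur) ||
      is.na(header_bytes) || header_bytes != 256L * (ns + 1L))
    stop("unreadable or corrupt EDF header in ", path)
  rd_field <- function(w) {
    vapply(seq_len(ns), function(i) trimws(rd_str(w)), character(1))
  }
  labels <- rd_field(16)
  rd_field(80)                       # transducer
  rd_field(8)                        # physical dimension
  pmin <- as.numeric(rd_field(8))
  pmax <- as.numeric(rd_field(8))
  dmin <- as.numeric(rd_field(8))
  dmax <- as.numeric(rd_field(8))
  rd_field(80)                       # prefiltering
  spr <- as.integer(rd_field(8))     # samples per record
  rd_field(32)                       # reserved

  want <- names(montage)
  missing_ch <- setdiff(want, labels)
  if (length(missing_ch))
    stop("channel(s) not present in EDF file: ",
         paste(missing_ch, collapse = ", "))
  idx <- match(want, labels)

  raw16 <- readBin(con, "integer", n = n_records * sum(spr), size = 2,
                   signed = TRUE, endian = "little")
  offs <- c(0L, cumsum(spr))
  per_rec <- sum(spr)
  sig <- vector("list", length(want))
  for (k in seq_along(want)) {
    i <- idx[k]
    pick <- unlist(lapply(seq_len(n_records) - 1L, function(r) {
      r * per_rec + offs[i] + seq_len(spr[i])
    }))
    dig <- raw16[pick]
    scale <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    sig[[k]] <- (dig - dmin[i]) * scale + pmin[i]
  }
  rates <- spr[idx] / record_dur
  sf <- max(rates)
  for (k in seq_along(sig)) {
    if (rates[k] < sf) sig[[k]] <- resample_poly(sig[[k]], sf, rates[k])
  }
  nmin <- min(lengths(sig))
  signals <- do.call(rbind, lapply(sig, function(s) s[seq_len(nmin)]))
  new_recording(signals, sf, want, montage,
                meta = list(file = path, edf_version = version))
}

#' Write a recording as EDF
#'
#' Fixture-grade EDF writer: 1-s data records, 16-bit samples, per-channel
#' physical scaling over the data range.  All channels must share a single
#' integer sampling rate and the recording is truncated to whole seconds.
#'
#' @param rec a [new_recording()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  sf <- rec$sfreq
  if (abs(sf - round(sf)) > 1e-9)
    stop("write_edf requires an integer sampling rate")
  sf <- as.integer(round(sf))
  ns <- nrow(rec$signals)
  n_records <- n_samples(rec) %/% sf
  if (n_records < 1L) stop("recording shorter than one data record")
  x <- rec$signals[, seq_len(n_records * sf), drop = FALSE]
  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  pmin <- signif(pmin - 1e-6 * pmax(abs(pmin), 1), 7)
  pmax <- signif(pmax + 1e-6 * pmax(abs(pmax), 1), 7)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad("Startdate 01-JAN-2000 synthetic", 80))
  wr(edf_pad("01.01.00", 8)); wr(edf_pad("00.00.00", 8))
  wr(edf_num(256L * (ns + 1L), 8))
  wr(edf_pad("", 44))
  wr(edf_num(n_records, 8))
  wr(edf_num(1, 8))
  wr(edf_num(ns, 4))
  wrf <- function(vals, w) for (v in vals) wr(edf_pad(v, w))
  wrf(rec$channel_names, 16)
  wrf(rep("", ns), 80)
  wrf(rep("uV", ns), 8)
  wrf(format(pmin, scientific = FALSE, trim = TRUE, digits = 7), 8)
  wrf(format(pmax, scientific = FALSE, trim = TRUE, digits = 7), 8)
  wrf(rep(dmin, ns), 8)
  wrf(rep(dmax, ns), 8)
  wrf(rep("", ns), 80)
  wrf(rep(sf, ns), 8)
  wrf(rep("", ns), 32)

  dig <- matrix(0L, nrow = ns, ncol = ncol(x))
  for (i in seq_len(ns)) {
    d <- (x[i, ] - pmin[i]) / (pmax[i] - pmin[i]) * (dmax - dmin) + dmin
    dig[i, ] <- as.integer(pmin(pmax(round(d), dmin), dmax))
  }
  out <- integer(ns * ncol(x))
  pos <- 0L
  for (r in seq_len(n_records) - 1L) {
    for (i in seq_len(ns)) {
      out[pos + seq_len(sf)] <- dig[i, r * sf + seq_len(sf)]
      pos <- pos + sf
    }
  }
  writeBin(out, con, size = 2, endian = "little")
  invisible(path)
}
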