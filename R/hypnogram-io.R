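# Hypnogram file dialects.  Three plain-text dialects are supported, all
# with exact round-trip behaviour:
#   "lines"       one stage token per line (whitespace-separated tokens are
#                 also accepted on read)
#   "csv"         CSV with header `epoch,stage` (epoch is 0-based)
#   "annotations" CSV with header `onset,duration,stage`; durations must be
#                 multiples of 30 s

#' Default stage token map
#'
#' Maps common AASM and Rechtschaffen & Kales spellings onto the canonical
#' vocabulary.  Users may extend or override entries; tokens not present in
#' the map are read as `UNKNOWN` (with a warning).
#'
#' @return Named character vector: token (upper-case) -> canonical stage.
#' @export
default_stage_token_map <- function() {
  c("W" = "W", "WAKE" = "W", "WK" = "W", "0" = "W",
    "N1" = "N1", "S1" = "N1", "1" = "N1",
    "N2" = "N2", "S2" = "N2", "2" = "N2",
    "N3" = "N3", "S3" = "N3", "3" = "N3", "S4" = "N3", "N4" = "N3", "4" = "N3",
    "REM" = "REM", "R" = "REM", "5" = "REM",
    "UNKNOWN" = "UNKNOWN", "?" = "UNKNOWN", "UNS" = "UNKNOWN",
    "MT" = "UNKNOWN", "MOVEMENT" = "UNKNOWN")
}

map_tokens <- function(tokens, token_map) {
  out <- unname(token_map[toupper(tokens)])
  bad <- is.na(out)
  if (any(bad)) {
    warning("unmappable stage token(s) read as UNKNOWN: ",
            paste(unique(tokens[bad]), collapse = ", "))
    out[bad] <- "UNKNOWN"
  }
  out
}

#' Read a hypnogram file
#'
#' @param path input file.
#' @param dialect one of `"lines"`, `"csv"`, `"annotations"` (see file
#'   header comments for the formats).
#' @param token_map stage token map, see [default_stage_token_map()].
#' @return A [new_hypnogram()] object (one stage per 30-s epoch).
#' @export
read_hypnogram <- function(path, dialect = c("lines", "csv", "annotations"),
                           token_map = default_stage_token_map()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("hypnogram file not found: ", path)
  if (dialect == "lines") {
    tokens <- scan(path, what = character(), quiet = TRUE)
    if (!length(tokens)) stop("empty hypnogram file: ", path)
    return(new_hypnogram(map_tokens(tokens, token_map)))
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty hypnogram file: ", path)
  if (dialect == "csv") {
    if (!all(c("epoch", "stage") %in% names(df)))
      stop("csv dialect requires header `epoch,stage`")
    df <- df[order(df$epoch), , drop = FALSE]
    return(new_hypnogram(map_tokens(as.character(df$stage), token_map)))
  }
  if (!all(c("onset", "duration", "stage") %in% names(df)))
    stop("annotations dialect requires header `onset,duration,stage`")
  bad <- which(df$duration <= 0 | df$duration %% 30 != 0)
  if (length(bad))
    stop("annotation duration not a positive multiple of 30 s at row ",
         bad[1], " (duration=", df$duration[bad[1]], ")")
  df <- df[order(df$onset), , drop = FALSE]
  stages <- map_tokens(as.character(df$stage), token_map)
  new_hypnogram(rep(stages, times = df$duration %/% 30))
}

#' Write a hypnogram file
#'
#' Inverse of [read_hypnogram()]; every dialect round-trips exactly.
#'
#' @param hyp a [new_hypnogram()] object.
#' @param path output file.
#' @param dialect one of `"lines"`, `"csv"`, `"annotations"`.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path,
                            dialect = c("lines", "csv", "annotations")) {
  dialect <- match.arg(dialect)
  stopifnot(is_hypnogram(hyp))
  if (!length(hyp)) stop("refusing to write an empty hypnogram")
  stages <- as.character(unclass(hyp))
  if (dialect == "lines") {
    writeLines(stages, path)
  } else if (dialect == "csv") {
    write.csv(data.frame(epoch = seq_along(stages) - 1L, stage = stages),
              path, row.names = FALSE, quote = FALSE)
  } else {
    r <- rle(stages)
    ends <- cumsum(r$lengths)
    onsets <- (ends - r$lengths) * 30L
    write.csv(data.frame(onset = onsets, duration = r$lengths * 30L,
                         stage = r$values),
              path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Rescore a Rechtschaffen & Kales hypnogram to AASM
#'
#' Maps `S1 -> N1`, `S2 -> N2`, `S3 -> N3`, `S4 -> N3`, keeps `W`/`REM`,
#' and turns movement time (`MT`) into `UNKNOWN`.  AASM labels already in
#' the input pass through unchanged, so the mapping is idempotent.
#'
#' @param stages character vector over the R&K vocabulary
#'   `W, S1, S2, S3, S4, REM, MT` (AASM labels also accepted).
#' @return A [new_hypnogram()] of the same length.
#' @export
map_rk_to_aasm <- function(stages) {
  stages <- toupper(as.character(stages))
  map <- c("W" = "W", "S1" = "N1", "S2" = "N2", "S3" = "N3", "S4" = "N3",
           "REM" = "REM", "MT" = "UNKNOWN",
           "N1" = "N1", "N2" = "N2", "N3" = "N3", "UNKNOWN" = "UNKNOWN")
  out <- unname(map[stages])
  if (anyNA(out))
    stop("unknown R&K token(s): ",
         paste(unique(stages[is.na(out)]), collapse = ", "))
  new_hypnogram(out)
}
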