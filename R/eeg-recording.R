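#' EEG recording container
#'
#' A multichannel recording: a channels x samples matrix in microvolts, the
#' channel labels, the sampling rate and the recording start time on the
#' session clock (ms). The session clock ties EEG samples to gaze
#' timestamps and trial onsets.
#'
#' @param data Numeric matrix, channels x samples, µV.
#' @param channels Character vector of channel labels (length = rows).
#' @param srate_hz Sampling rate, Hz (> 0).
#' @param start_ms Recording start on the session clock, ms.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, channels, srate_hz, start_ms = 0) {
  data <- as.matrix(data)
  stopifnot(length(channels) == nrow(data), srate_hz > 0)
  structure(list(data = data, channels = as.character(channels),
                 srate_hz = srate_hz, start_ms = start_ms),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (start %g ms)\n",
              nrow(x$data), ncol(x$data), x$srate_hz, x$start_ms))
  invisible(x)
}

#' Select a channel subset by label
#'
#' @param rec An [eeg_recording()].
#' @param channels Labels to keep, in the requested order.
#' @return An [eeg_recording()] restricted to those channels.
#' @export
select_channels <- function(rec, channels) {
  idx <- match(channels, rec$channels)
  if (anyNA(idx))
    stop("unknown channel label(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  eeg_recording(rec$data[idx, , drop = FALSE], channels,
                rec$srate_hz, rec$start_ms)
}

#' Headered-CSV EEG I/O
#'
#' Plain-text interchange format: two comment lines carry the sampling rate
#' and start time, then a CSV matrix with one column per channel (header =
#' labels) and one row per sample.
#'
#' @param rec An [eeg_recording()].
#' @param path File path.
#' @export
write_eeg_csv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# srate_hz=%.10g", rec$srate_hz),
               sprintf("# start_ms=%.10g", rec$start_ms)), con)
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channels
  utils::write.csv(df, con, row.names = FALSE)
}

#' @rdname write_eeg_csv
#' @export
read_eeg_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  getval <- function(key) {
    line <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(line) != 1) stop("missing header line for ", key, " in ", path)
    as.numeric(sub(paste0("^# ", key, "="), "", line))
  }
  srate <- getval("srate_hz"); start <- getval("start_ms")
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  eeg_recording(t(as.matrix(df)), names(df), srate, start)
}
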