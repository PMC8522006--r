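#' Construct a multi-channel EEG recording
#'
#' Container for a labeled multi-channel time series in microvolts.
#' Channels are columns of a numeric matrix; all channels share one
#' sampling rate. The study layout has 11 channels: the eight
#' around-the-ear electrodes `R1`..`R8` (recorded against a right-mastoid
#' reference), the frontal scalp electrode `Fpz`, and two periocular EOG
#' channels `EOG_L`, `EOG_R`, sampled at 250 Hz.
#'
#' @param data numeric matrix (samples x channels) with unique column
#'   names, or a data frame of numeric columns. Amplitude in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param start_time optional `POSIXct` start timestamp.
#' @return An object of class `eeg_recording` with elements `data`
#'   (matrix), `channel_labels`, `fs` and `start_time`.
#' @examples
#' rec <- recording(cbind(Fpz = sin(2 * pi * 10 * (0:249) / 250)), fs = 250)
#' rec
#' @export
recording <- function(data, fs, start_time = NULL) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data) || !is.numeric(data)) {
    stop_earsleep("data must be a numeric samples-by-channels matrix",
                  "earsleep_validation_error")
  }
  labels <- colnames(data)
  if (is.null(labels) || anyNA(labels) || any(labels == "")) {
    stop_earsleep("every channel needs a non-empty label (column name)",
                  "earsleep_validation_error")
  }
  if (anyDuplicated(labels)) {
    stop_earsleep("channel labels must be unique", "earsleep_validation_error")
  }
  if (!is_scalar_number(fs) || fs <= 0) {
    stop_earsleep("fs must be a positive sampling rate in Hz",
                  "earsleep_validation_error")
  }
  structure(
    list(data = data, channel_labels = labels, fs = fs,
         start_time = start_time),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.2f h)\n",
              ncol(x$data), nrow(x$data), x$fs,
              nrow(x$data) / x$fs / 3600))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples per channel
#' @param rec an `eeg_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  nrow(rec$data)
}

#' Extract one channel as a numeric vector
#' @param rec an `eeg_recording`.
#' @param label channel label.
#' @return Numeric vector of samples.
#' @export
channel <- function(rec, label) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!label %in% rec$channel_labels) {
    stop_earsleep(sprintf("channel '%s' not present in recording", label),
                  "earsleep_lookup_error")
  }
  rec$data[, label]
}
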