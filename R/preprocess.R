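#' Bandpass filter specification
#'
#' The signal-conditioning stage is a zero-phase (forward-backward)
#' 4th-order Butterworth bandpass with a 0.5-40 Hz passband: the
#' high-pass edge removes electrode drift, the low-pass edge removes
#' high-frequency noise while keeping every scoring-relevant rhythm
#' (delta through sleep-spindle sigma).
#'
#' @param order filter order of the causal design (default 4).
#' @param low_hz lower passband edge in Hz (default 0.5).
#' @param high_hz upper passband edge in Hz (default 40).
#' @param zero_phase apply the filter forward and backward so the net
#'   phase response is zero (default `TRUE`). The magnitude response is
#'   then squared, so each corner sits at -6 dB instead of -3 dB.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, low_hz = 0.5, high_hz = 40,
                        zero_phase = TRUE) {
  if (!is_scalar_number(order) || order < 1 || order != round(order)) {
    stop_earsleep("order must be a positive integer", "earsleep_design_error")
  }
  if (!is_scalar_number(low_hz) || !is_scalar_number(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz) {
    stop_earsleep("need 0 < low_hz < high_hz", "earsleep_design_error")
  }
  structure(list(order = as.integer(order), low_hz = low_hz,
                 high_hz = high_hz, kind = "bandpass",
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Forward-backward IIR filtering with odd-symmetric (point-reflected)
# signal extension at both ends. The pad must outlast the slowest
# transient of the design -- for a 0.5 Hz high-pass edge that is seconds,
# not samples -- so it is sized in cycles of the low cutoff rather than
# in multiples of the filter order.
filtfilt_padded <- function(b, a, x, padlen) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  if (padlen > 0L) {
    pre  <- 2 * x[1L] - x[(padlen + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
    y <- c(pre, x, post)
  } else {
    y <- x
  }
  y <- as.numeric(signal::filter(b, a, y))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  if (padlen > 0L) y[(padlen + 1L):(padlen + n)] else y
}

#' Zero-phase Butterworth bandpass filtering
#'
#' Filters every channel with the Butterworth design of `spec`, applied
#' forward and then backward so the output has zero net phase shift.
#' Signal length and sampling rate are preserved. Startup transients are
#' suppressed by odd-symmetric signal extension covering six cycles of
#' the low cutoff at both ends before filtering.
#'
#' @param rec an [recording()].
#' @param spec a [filter_spec()]; `high_hz` must lie below the Nyquist
#'   frequency `rec$fs / 2`.
#' @return The filtered [recording()].
#' @export
bandpass_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  nyq <- rec$fs / 2
  if (spec$high_hz >= nyq) {
    stop_earsleep(sprintf(
      "upper edge %g Hz must be below the Nyquist frequency %g Hz",
      spec$high_hz, nyq), "earsleep_design_error")
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq,
                       type = "pass")
  padlen <- as.integer(ceiling(6 * rec$fs / spec$low_hz))
  out <- rec$data
  for (j in seq_len(ncol(out))) {
    if (spec$zero_phase) {
      out[, j] <- filtfilt_padded(bf$b, bf$a, rec$data[, j], padlen)
    } else {
      out[, j] <- as.numeric(signal::filter(bf$b, bf$a, rec$data[, j]))
    }
  }
  recording(out, fs = rec$fs, start_time = rec$start_time)
}

#' Downsample a recording by integer decimation
#'
#' Keeps every `fs / target_fs`-th sample starting at the first. No
#' additional anti-alias filter is applied: the pipeline's 40 Hz
#' low-pass already bounds content well below the 62.5 Hz Nyquist of the
#' 125 Hz target rate, matching the order of operations of the
#' preprocessing chain.
#'
#' @param rec an [recording()] whose `fs` is an integer multiple of
#'   `target_fs`.
#' @param target_fs target sampling rate in Hz (default 125).
#' @return The decimated [recording()].
#' @export
downsample <- function(rec, target_fs = 125) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is_scalar_number(target_fs) || target_fs <= 0) {
    stop_earsleep("target_fs must be a positive rate in Hz",
                  "earsleep_resampling_error")
  }
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1) {
    stop_earsleep(sprintf(
      "fs %g Hz is not an integer multiple of target %g Hz",
      rec$fs, target_fs), "earsleep_resampling_error")
  }
  ratio <- as.integer(round(ratio))
  idx <- seq(1L, nrow(rec$data), by = ratio)
  recording(rec$data[idx, , drop = FALSE], fs = target_fs,
            start_time = rec$start_time)
}

#' Remove the DC offset of an epoch
#'
#' Subtracts the mean over all samples of the epoch, the per-epoch
#' offset estimate used before correlating grapho-element traces.
#' Idempotent and linear; the output mean is zero to numeric precision.
#'
#' @param x numeric vector of samples (non-empty).
#' @return `x` minus its mean.
#' @export
remove_dc <- function(x) {
  if (!is.numeric(x) || length(x) == 0L) {
    stop_earsleep("epoch must be a non-empty numeric vector",
                  "earsleep_validation_error")
  }
  x - mean(x)
}
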