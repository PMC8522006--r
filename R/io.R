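#' Read a multi-channel recording from EDF or CSV
#'
#' EDF is the standard binary carrier understood by sleep tooling; the
#' CSV dialect (wide table, first column `time` in seconds, one column
#' per channel, header row of labels) is a dependency-light,
#' human-inspectable fallback used for small fixtures.
#'
#' @param path file path.
#' @param format `"edf"`, `"csv"` or `"auto"` (by file extension).
#' @return An [recording()] object with amplitudes in microvolts.
#' @seealso [write_recording()]
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_earsleep(sprintf("file not found: %s", path), "earsleep_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") return(read_edf(path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "time") {
    stop_earsleep("recording CSV must have a leading 'time' column plus channels",
                  "earsleep_format_error")
  }
  tm <- df[[1L]]
  if (nrow(df) < 2L) {
    stop_earsleep("recording CSV needs at least two samples",
                  "earsleep_format_error")
  }
  dt <- diff(tm)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt) + 1e-9) {
    stop_earsleep("time column is not uniformly increasing",
                  "earsleep_integrity_error")
  }
  fs <- (nrow(df) - 1) / (tm[nrow(df)] - tm[1L])
  data <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(data)) {
    stop_earsleep("non-numeric sample values in recording CSV",
                  "earsleep_format_error")
  }
  recording(data, fs = fs)
}

#' Write a recording to EDF or CSV
#'
#' EDF output is plain continuous EDF with physical dimension `uV`,
#' 16-bit samples and 1-second data records; recordings are zero-padded
#' to a whole number of seconds, so round trips are exact up to one
#' digitization step of the per-channel physical range. CSV output is
#' the wide time-plus-channels dialect of [read_recording()].
#'
#' @param rec an [recording()] object.
#' @param path output path.
#' @param format `"edf"`, `"csv"` or `"auto"` (by extension).
#' @return The path, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "csv")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "edf") return(invisible(write_edf(rec, path)))
  df <- data.frame(time = (seq_len(nrow(rec$data)) - 1) / rec$fs,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(rec$data, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a hypnogram from CSV
#'
#' Expects columns `epoch_index,stage`, one 30-s epoch per row, stage
#' labels from [sleep_stages()]. Rows are used in file order; unknown
#' labels are rejected with the offending values named.
#'
#' @param path CSV file.
#' @param epoch_length epoch duration in seconds (default 30).
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_length = 30) {
  df <- utils::read.csv(path, colClasses = c("integer", "character"))
  if (!all(c("epoch_index", "stage") %in% names(df))) {
    stop_earsleep("hypnogram CSV must have columns epoch_index,stage",
                  "earsleep_format_error")
  }
  hypnogram(df$stage, epoch_length = epoch_length)
}

#' Write a hypnogram to CSV
#' @param h a [hypnogram()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(inherits(h, "hypnogram"))
  utils::write.csv(
    data.frame(epoch_index = seq_along(h$stages) - 1L, stage = h$stages),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

valid_event_labels <- c("k_complex", "spindle")

validate_events <- function(ev) {
  need <- c("onset_s", "duration_s", "label", "channel")
  if (!all(need %in% names(ev))) {
    stop_earsleep(sprintf("event table must have columns %s",
                          paste(need, collapse = ",")),
                  "earsleep_format_error")
  }
  if (nrow(ev) == 0L) return(ev)
  if (any(!is.finite(ev$onset_s)) || any(ev$onset_s < 0)) {
    stop_earsleep("event onsets must be finite and >= 0 s",
                  "earsleep_validation_error")
  }
  if (any(!is.finite(ev$duration_s)) || any(ev$duration_s <= 0)) {
    stop_earsleep("event durations must be finite and > 0 s",
                  "earsleep_validation_error")
  }
  bad <- setdiff(unique(ev$label), valid_event_labels)
  if (length(bad) > 0L) {
    stop_earsleep(sprintf("unknown grapho-element label(s): %s (allowed: %s)",
                          paste(bad, collapse = ", "),
                          paste(valid_event_labels, collapse = ", ")),
                  "earsleep_validation_error")
  }
  ev
}

#' Read grapho-element event annotations from CSV
#'
#' Events are typed intervals (`onset_s,duration_s,label,channel`) with
#' labels `k_complex` or `spindle`, the two N2 hallmarks used in the
#' correlation analysis. The returned table is sorted by onset.
#'
#' @param path CSV file.
#' @return A data frame with columns `onset_s`, `duration_s`, `label`,
#'   `channel`, sorted by onset.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, colClasses = c("numeric", "numeric",
                                             "character", "character"))
  df <- validate_events(df)
  df <- df[order(df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write grapho-element event annotations to CSV
#' @param events event data frame as returned by [read_events()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path) {
  events <- validate_events(as.data.frame(events))
  events <- events[order(events$onset_s),
                   c("onset_s", "duration_s", "label", "channel"),
                   drop = FALSE]
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stage confusion matrix from CSV
#'
#' Expects a label-indexed square table (first column: row stage labels;
#' header: column stage labels) of non-negative integer counts over the
#' [sleep_stages()] alphabet. Rows are one rating, columns the other.
#' The result is reordered to the canonical stage order so matrices from
#' different files are comparable cell by cell.
#'
#' @param path CSV file.
#' @return A `confusion_matrix` (6 x 6 integer matrix with stage dimnames).
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  rn <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- rn
  as_confusion_matrix(m)
}

#' Write a stage confusion matrix to CSV
#' @param m a `confusion_matrix` or square labeled count matrix.
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_confusion_csv <- function(m, path) {
  m <- as_confusion_matrix(m)
  df <- data.frame(stage = rownames(m), check.names = FALSE)
  df <- cbind(df, as.data.frame(unclass(m), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
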