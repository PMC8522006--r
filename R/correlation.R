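#' Extract grapho-element epochs from a recording
#'
#' Cuts the annotated K-complex / sleep-spindle intervals out of the
#' recording: the reference trace from `Fpz` and the raw traces from
#' `R1`..`R8`, each over the sample window
#' `[round(onset * fs), round((onset + duration) * fs))` and with the
#' per-epoch DC offset removed ([remove_dc()]). Epoch windows follow the
#' annotated onset and offset exactly (variable length, no padding).
#'
#' @param rec an [recording()] containing `Fpz` and `R1`..`R8`.
#' @param events event table as returned by [read_events()]; every event
#'   must lie within the recording.
#' @return A list of `event_epoch` objects with elements `event` (the
#'   annotation row), `reference` (Fpz trace), `raw` (samples x 8 matrix
#'   of ear-channel traces) and `fs`.
#' @export
extract_epochs <- function(rec, events) {
  stopifnot(inherits(rec, "eeg_recording"))
  events <- validate_events(as.data.frame(events))
  ear <- paste0("R", 1:8)
  need <- c("Fpz", ear)
  missing <- setdiff(need, rec$channel_labels)
  if (length(missing) > 0L) {
    stop_earsleep(sprintf("recording lacks channel(s): %s",
                          paste(missing, collapse = ", ")),
                  "earsleep_lookup_error")
  }
  n <- nrow(rec$data)
  fs <- rec$fs
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    from <- round(events$onset_s[i] * fs)
    to <- round((events$onset_s[i] + events$duration_s[i]) * fs)
    if (to > n || from < 0) {
      stop_earsleep(sprintf(
        "event %d (%s at %.3f s, %.3f s long) lies outside the recording (%.3f s)",
        i, events$label[i], events$onset_s[i], events$duration_s[i], n / fs),
        "earsleep_bounds_error")
    }
    if (to - from < 2L) {
      stop_earsleep(sprintf("event %d spans fewer than 2 samples", i),
                    "earsleep_validation_error")
    }
    idx <- (from + 1L):to
    raw <- rec$data[idx, ear, drop = FALSE]
    raw <- sweep(raw, 2L, colMeans(raw))
    out[[i]] <- structure(
      list(event = events[i, , drop = FALSE],
           reference = remove_dc(rec$data[idx, "Fpz"]),
           raw = raw, fs = fs),
      class = "event_epoch")
  }
  out
}

#' Correlate one epoch against every ear-channel combination
#'
#' Pearson product-moment correlation between the epoch's Fpz reference
#' trace and the derived trace of each single / bipolar ear-channel
#' combination. A combination whose derived trace has zero variance has
#' no defined correlation; it is reported as `NA` (missing), never as 0.
#'
#' @param epoch an `event_epoch` from [extract_epochs()].
#' @param combos list of combination [derivation()]s over `R1`..`R8`
#'   (default [enumerate_combinations()]).
#' @return Named numeric vector of correlations, one per combination.
#' @export
correlate_epoch <- function(epoch, combos = enumerate_combinations()) {
  stopifnot(inherits(epoch, "event_epoch"))
  ref <- epoch$reference
  if (stats::sd(ref) == 0) {
    stop_earsleep("reference trace has zero variance; correlations undefined",
                  "earsleep_validation_error")
  }
  r <- vapply(combos, function(d) {
    y <- as.vector(epoch$raw[, names(d$weights), drop = FALSE] %*% d$weights)
    if (stats::sd(y) == 0) return(NA_real_)
    stats::cor(ref, y)
  }, numeric(1))
  names(r) <- vapply(combos, `[[`, "", "label")
  r
}

#' Average correlation coefficients on the Fisher-Z scale
#'
#' Correlations are averaged as `tanh(mean(atanh(r)))`: the Fisher
#' transform makes the sampling distribution of r approximately normal,
#' so the mean is taken on that scale and mapped back with the
#' hyperbolic tangent. Values of exactly +/-1 are clipped to
#' +/-(1 - 1e-12) so the transform stays finite; missing values
#' (undefined correlations) are excluded rather than imputed.
#'
#' @param rs numeric vector of correlation coefficients in `[-1, 1]`;
#'   `NA`s are dropped.
#' @return The back-transformed average correlation.
#' @examples
#' fisher_average(c(0.5, 0.9))
#' @export
fisher_average <- function(rs) {
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0L) {
    stop_earsleep("no correlation values to average",
                  "earsleep_validation_error")
  }
  if (any(abs(rs) > 1)) {
    stop_earsleep("correlations must lie in [-1, 1]",
                  "earsleep_validation_error")
  }
  lim <- 1 - 1e-12
  rs <- pmin(pmax(rs, -lim), lim)
  tanh(mean(atanh(rs)))
}

#' Correlation topography of a grapho-element
#'
#' The central question of the correlation analysis: which ear-channel
#' combination best represents the frontal (Fpz) waveform of annotated
#' K-complexes or sleep spindles? Per combination, the per-epoch Pearson
#' correlations are Fisher-Z averaged over all epochs of the requested
#' element. For a grand average over participants, per-participant
#' averages are Fisher-Z averaged once more.
#'
#' @param rec an [recording()], or a list of recordings (one per
#'   participant) for `grouping = "grand"`.
#' @param events event table, or a list of event tables parallel to
#'   `rec`.
#' @param element_label `"k_complex"` or `"spindle"`.
#' @param grouping `"participant"` (single recording) or `"grand"`
#'   (average of per-participant averages).
#' @param combos combination derivations (default
#'   [enumerate_combinations()]).
#' @return A data frame of class `correlation_topography` with columns
#'   `combination`, `element`, `n_epochs`, `r_avg` (one row per
#'   combination, in enumeration order).
#' @export
topography <- function(rec, events, element_label = c("k_complex", "spindle"),
                       grouping = c("participant", "grand"),
                       combos = enumerate_combinations()) {
  element_label <- match.arg(element_label)
  grouping <- match.arg(grouping)
  labels <- vapply(combos, `[[`, "", "label")

  per_participant <- function(rec1, ev1) {
    ev1 <- validate_events(as.data.frame(ev1))
    ev1 <- ev1[ev1$label == element_label, , drop = FALSE]
    if (nrow(ev1) == 0L) {
      stop_earsleep(sprintf("no events labeled '%s'", element_label),
                    "earsleep_validation_error")
    }
    epochs <- extract_epochs(rec1, ev1)
    rmat <- vapply(epochs, correlate_epoch, numeric(length(combos)),
                   combos = combos)
    rmat <- matrix(rmat, nrow = length(combos))  # combos x epochs
    list(r = apply(rmat, 1L, fisher_average), n = length(epochs))
  }

  if (grouping == "grand") {
    if (!is.list(rec) || inherits(rec, "eeg_recording")) {
      rec <- list(rec); events <- list(events)
    }
    parts <- Map(per_participant, rec, events)
    rmat <- vapply(parts, `[[`, numeric(length(combos)), "r")
    rmat <- matrix(rmat, nrow = length(combos))
    r_avg <- apply(rmat, 1L, fisher_average)
    n_epochs <- sum(vapply(parts, `[[`, numeric(1), "n"))
  } else {
    p <- per_participant(rec, events)
    r_avg <- p$r
    n_epochs <- p$n
  }
  structure(
    data.frame(combination = labels, element = element_label,
               n_epochs = n_epochs, r_avg = r_avg,
               stringsAsFactors = FALSE),
    class = c("correlation_topography", "data.frame")
  )
}
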