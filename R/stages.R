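#' Canonical sleep-stage alphabet
#'
#' The six hypnogram categories used throughout the package, in the
#' canonical order `Art, W, N1, N2, N3, REM` (artifact, wake, non-REM
#' depths 1-3, rapid eye movement). Every confusion matrix, transition
#' matrix and scorer-noise kernel is indexed in this order so that
#' matrices are comparable cell by cell.
#'
#' @return Character vector of the six stage labels.
#' @export
sleep_stages <- function() {
  c("Art", "W", "N1", "N2", "N3", "REM")
}

validate_stage_labels <- function(x, what = "stage") {
  bad <- setdiff(unique(as.character(x)), sleep_stages())
  if (length(bad) > 0L) {
    stop_earsleep(
      sprintf("unknown %s label(s): %s (allowed: %s)",
              what, paste(bad, collapse = ", "),
              paste(sleep_stages(), collapse = ", ")),
      "earsleep_validation_error"
    )
  }
  invisible(x)
}

#' Construct a hypnogram
#'
#' A hypnogram is the ordered sequence of sleep-stage labels assigned to
#' consecutive fixed-length (by convention 30 s) epochs of a night.
#'
#' @param stages character vector over the alphabet of [sleep_stages()].
#' @param epoch_length epoch duration in seconds (default 30).
#' @return An object of class `hypnogram`.
#' @seealso [read_hypnogram()], [simulate_hypnogram()]
#' @export
hypnogram <- function(stages, epoch_length = 30) {
  stages <- as.character(stages)
  if (length(stages) == 0L) {
    stop_earsleep("a hypnogram needs at least one epoch", "earsleep_validation_error")
  }
  validate_stage_labels(stages)
  if (!is_scalar_number(epoch_length) || epoch_length <= 0) {
    stop_earsleep("epoch_length must be a positive number of seconds",
                  "earsleep_validation_error")
  }
  structure(list(stages = stages, epoch_length = epoch_length),
            class = "hypnogram")
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = sleep_stages()))
  cat(sprintf("<hypnogram> %d epochs of %g s (%.2f h)\n",
              length(x$stages), x$epoch_length,
              length(x$stages) * x$epoch_length / 3600))
  print(tab)
  invisible(x)
}

#' Concatenate hypnograms across participants
#'
#' Agreement over a cohort is computed on epochs pooled across
#' participants; this joins per-participant hypnograms end to end.
#' All inputs must share the same epoch length.
#'
#' @param hyps list of `hypnogram` objects.
#' @return A single `hypnogram`.
#' @export
concatenate_hypnograms <- function(hyps) {
  if (length(hyps) == 0L) {
    stop_earsleep("no hypnograms to concatenate", "earsleep_validation_error")
  }
  stopifnot(all(vapply(hyps, inherits, logical(1), "hypnogram")))
  els <- vapply(hyps, function(h) h$epoch_length, numeric(1))
  if (length(unique(els)) != 1L) {
    stop_earsleep("hypnograms have differing epoch lengths",
                  "earsleep_validation_error")
  }
  hypnogram(unlist(lapply(hyps, `[[`, "stages")), epoch_length = els[[1]])
}
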