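#' Define a virtual-channel derivation
#'
#' A derivation is a signed linear combination of recorded channels,
#' relabeled after the scalp position it approximates. Example: the
#' around-the-ear estimate of F4 referenced to the right mastoid is
#' `F4_M2 = (R1 + R2)/2 - R6`.
#'
#' @param label name of the virtual channel.
#' @param weights named numeric vector mapping raw channel labels to
#'   signed coefficients; at least one weight must be nonzero.
#' @return An object of class `derivation`.
#' @export
derivation <- function(label, weights) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop_earsleep("derivation label must be a single non-empty string",
                  "earsleep_validation_error")
  }
  if (!is.numeric(weights) || is.null(names(weights)) ||
      any(!nzchar(names(weights))) || anyDuplicated(names(weights))) {
    stop_earsleep("weights must be a numeric vector with unique channel names",
                  "earsleep_validation_error")
  }
  if (all(weights == 0)) {
    stop_earsleep("derivation needs at least one nonzero weight",
                  "earsleep_validation_error")
  }
  structure(list(label = label, weights = weights), class = "derivation")
}

#' Define a montage (ordered set of derivations)
#'
#' @param derivations list of [derivation()] objects with unique labels.
#' @param name optional montage name.
#' @return An object of class `montage_spec`.
#' @export
montage_spec <- function(derivations, name = NULL) {
  stopifnot(is.list(derivations),
            all(vapply(derivations, inherits, logical(1), "derivation")))
  labels <- vapply(derivations, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop_earsleep("derivation labels within a montage must be unique",
                  "earsleep_validation_error")
  }
  structure(list(derivations = derivations, name = name),
            class = "montage_spec")
}

#' @export
print.montage_spec <- function(x, ...) {
  cat(sprintf("<montage_spec> %s (%d derivations)\n",
              if (is.null(x$name)) "<unnamed>" else x$name,
              length(x$derivations)))
  for (d in x$derivations) {
    w <- d$weights[d$weights != 0]
    terms <- sprintf("%+g*%s", unname(w), names(w))
    cat(sprintf("  %-10s = %s\n", d$label, paste(terms, collapse = " ")))
  }
  invisible(x)
}

#' Standard study montages
#'
#' The three channel layouts used for sleep scoring:
#' \describe{
#'   \item{`Fpz+EOG`}{the frontal reference set: `Fpz`, `EOG_L`, `EOG_R`
#'     as unit-weight passthroughs.}
#'   \item{`cEEGrid`}{five EEG derivations built from the ear electrodes
#'     and relabeled after the PSG positions they extrapolate toward
#'     (all referenced to the right mastoid M2):
#'     `Fp2_M2 = R1`, `F4_M2 = (R1+R2)/2 - R6`,
#'     `C4_M2 = (R2+R3)/2 - (R6+R7)/2`, `P4_M2 = (R3+R4)/2 - R7`,
#'     `O2_M2 = R7 - R8`. `R1` is already mastoid-referenced at
#'     acquisition, so `Fp2_M2` needs no re-reference term.}
#'   \item{`cEEGrid+EOG`}{the `cEEGrid` layout plus the two EOG channels
#'     re-referenced to `R6` as a stand-in mastoid: `EOG_L_M2 = EOG_L - R6`,
#'     `EOG_R_M2 = EOG_R - R6`.}
#' }
#'
#' @param name one of `"Fpz+EOG"`, `"cEEGrid"`, `"cEEGrid+EOG"`.
#' @return A [montage_spec()].
#' @examples
#' build_standard_montage("cEEGrid")
#' @export
build_standard_montage <- function(name = c("Fpz+EOG", "cEEGrid", "cEEGrid+EOG")) {
  if (length(name) == 1L && !name %in% c("Fpz+EOG", "cEEGrid", "cEEGrid+EOG")) {
    stop_earsleep(sprintf("unknown montage layout '%s'", name),
                  "earsleep_lookup_error")
  }
  name <- match.arg(name)
  eeg <- list(
    derivation("Fp2_M2", c(R1 = 1)),
    derivation("F4_M2",  c(R1 = 0.5, R2 = 0.5, R6 = -1)),
    derivation("C4_M2",  c(R2 = 0.5, R3 = 0.5, R6 = -0.5, R7 = -0.5)),
    derivation("P4_M2",  c(R3 = 0.5, R4 = 0.5, R7 = -1)),
    derivation("O2_M2",  c(R7 = 1, R8 = -1))
  )
  ders <- switch(
    name,
    "Fpz+EOG" = list(
      derivation("Fpz",   c(Fpz = 1)),
      derivation("EOG_L", c(EOG_L = 1)),
      derivation("EOG_R", c(EOG_R = 1))
    ),
    "cEEGrid" = eeg,
    "cEEGrid+EOG" = c(eeg, list(
      derivation("EOG_L_M2", c(EOG_L = 1, R6 = -1)),
      derivation("EOG_R_M2", c(EOG_R = 1, R6 = -1))
    ))
  )
  montage_spec(ders, name = name)
}

#' Apply a montage to a recording
#'
#' Each output channel is the samplewise weighted sum of the referenced
#' raw channels. The operation is linear, preserves the sampling rate
#' and relabels channels with the derivation labels.
#'
#' @param rec an [recording()].
#' @param m a [montage_spec()].
#' @return A new [recording()] with one channel per derivation.
#' @export
apply_montage <- function(rec, m) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(m, "montage_spec"))
  needed <- unique(unlist(lapply(m$derivations, function(d) names(d$weights))))
  missing <- setdiff(needed, rec$channel_labels)
  if (length(missing) > 0L) {
    stop_earsleep(sprintf("montage references missing raw channel(s): %s",
                          paste(missing, collapse = ", ")),
                  "earsleep_lookup_error")
  }
  out <- matrix(0, nrow = nrow(rec$data), ncol = length(m$derivations))
  colnames(out) <- vapply(m$derivations, `[[`, "", "label")
  for (i in seq_along(m$derivations)) {
    w <- m$derivations[[i]]$weights
    out[, i] <- rec$data[, names(w), drop = FALSE] %*% w
  }
  recording(out, fs = rec$fs, start_time = rec$start_time)
}

#' Enumerate all single and bipolar ear-channel combinations
#'
#' For `n` electrodes this yields the `n` singletons plus the
#' `n*(n-1)/2` ordered bipolar pairs `Ri - Rj` (`i < j`), interleaved in
#' the conventional order `R1, R1-R2, R2, R1-R3, R2-R3, R3, ...`: for
#' each new electrode `Rk`, first the pairs `Ri-Rk` for `i < k`, then
#' the singleton `Rk`. For the 8-channel grid this gives the 36
#' combinations of the correlation topography.
#'
#' @param labels character vector of distinct raw channel labels
#'   (default `R1`..`R8`).
#' @return A list of [derivation()] objects (length `n + choose(n, 2)`).
#' @examples
#' length(enumerate_combinations())  # 36
#' @export
enumerate_combinations <- function(labels = paste0("R", 1:8)) {
  if (anyDuplicated(labels)) {
    stop_earsleep("combination labels must be distinct",
                  "earsleep_validation_error")
  }
  out <- list()
  for (k in seq_along(labels)) {
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        w <- c(1, -1)
        names(w) <- c(labels[i], labels[k])
        out[[length(out) + 1L]] <-
          derivation(paste0(labels[i], "-", labels[k]), w)
      }
    }
    w <- 1
    names(w) <- labels[k]
    out[[length(out) + 1L]] <- derivation(labels[k], w)
  }
  out
}

#' Serialize a montage to YAML
#'
#' The YAML layout maps each derivation label to its
#' `channel: weight` map, with the montage name under `name`.
#'
#' @param m a [montage_spec()].
#' @param path optional output file; if `NULL`, the YAML string is returned.
#' @return The YAML string (invisibly when written to a file).
#' @export
montage_to_yaml <- function(m, path = NULL) {
  stopifnot(inherits(m, "montage_spec"))
  obj <- list(
    name = m$name,
    derivations = stats::setNames(
      lapply(m$derivations, function(d) as.list(d$weights)),
      vapply(m$derivations, `[[`, "", "label")
    )
  )
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Deserialize a montage from YAML
#' @param path YAML file, or a YAML string produced by [montage_to_yaml()].
#' @return A [montage_spec()].
#' @export
montage_from_yaml <- function(path) {
  obj <- if (file.exists(path)) yaml::read_yaml(path) else yaml::yaml.load(path)
  ders <- lapply(names(obj$derivations), function(lbl) {
    w <- unlist(obj$derivations[[lbl]])
    derivation(lbl, w)
  })
  montage_spec(ders, name = obj$name)
}
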