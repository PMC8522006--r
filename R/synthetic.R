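#' Parameters of the synthetic sleep model
#'
#' Defaults emulate a typical healthy adult night at the study's
#' recording settings: 30-s epochs at 250 Hz, a first-order Markov stage
#' sequence with strong self-transitions, AASM-conventional
#' stage-dependent spectra (alpha in wake, theta in N1, spindle/K-complex
#' activity in N2, high-amplitude slow delta in N3, low-amplitude mixed
#' activity in REM, broadband bursts in artifact epochs) and N2
#' grapho-element rates of 2.5 spindles and 1.5 K-complexes per minute.
#'
#' @param stage_transition 6 x 6 row-stochastic matrix over
#'   [sleep_stages()] (rows: from-stage).
#' @param epoch_length epoch duration in seconds (default 30).
#' @param fs sampling rate in Hz (default 250).
#' @param stage_spectra named list per stage with elements `freq` (Hz),
#'   `amp` (oscillation amplitude, uV) and `background` (1/f-like
#'   background RMS, uV).
#' @param event_rates named vector `c(spindle=, k_complex=)` of events
#'   per minute of N2.
#' @param event_amps named vector of source-level event peak amplitudes
#'   in uV.
#' @param seed default integer seed used by the simulators.
#' @return An object of class `sleep_model_params`.
#' @export
sleep_model_params <- function(stage_transition = default_stage_transition(),
                               epoch_length = 30,
                               fs = 250,
                               stage_spectra = default_stage_spectra(),
                               event_rates = c(spindle = 2.5, k_complex = 1.5),
                               event_amps = c(spindle = 40, k_complex = 150),
                               seed = 1L) {
  validate_transition_matrix(stage_transition)
  if (!is_scalar_number(fs) || fs <= 0) {
    stop_earsleep("fs must be positive", "earsleep_validation_error")
  }
  fmax <- max(vapply(stage_spectra, function(s) s$freq, numeric(1)))
  if (fs <= 2 * fmax) {
    stop_earsleep("fs must exceed twice the fastest stage frequency",
                  "earsleep_validation_error")
  }
  if (any(event_rates < 0)) {
    stop_earsleep("event rates must be >= 0", "earsleep_validation_error")
  }
  structure(list(stage_transition = stage_transition,
                 epoch_length = epoch_length, fs = fs,
                 stage_spectra = stage_spectra,
                 event_rates = event_rates, event_amps = event_amps,
                 seed = as.integer(seed)),
            class = "sleep_model_params")
}

validate_transition_matrix <- function(P) {
  st <- sleep_stages()
  if (!is.matrix(P) || !all(dim(P) == length(st)) ||
      is.null(rownames(P)) || !identical(rownames(P), st) ||
      !identical(colnames(P), st)) {
    stop_earsleep("transition matrix must be 6 x 6 with canonical stage dimnames",
                  "earsleep_validation_error")
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stop_earsleep("transition matrix rows must be non-negative and sum to 1",
                  "earsleep_validation_error")
  }
  invisible(P)
}

#' Default stage-transition matrix
#'
#' Row-stochastic 30-s-epoch transition probabilities producing nights
#' with realistic bout structure: long N2/N3/REM bouts, brief N1
#' transitions, rare artifact epochs.
#'
#' @return 6 x 6 matrix over [sleep_stages()].
#' @export
default_stage_transition <- function() {
  st <- sleep_stages()
  P <- rbind(
    Art = c(0.300, 0.400, 0.100, 0.100, 0.050, 0.050),
    W   = c(0.005, 0.900, 0.085, 0.010, 0.000, 0.000),
    N1  = c(0.005, 0.090, 0.700, 0.190, 0.000, 0.015),
    N2  = c(0.005, 0.020, 0.030, 0.850, 0.070, 0.025),
    N3  = c(0.005, 0.005, 0.005, 0.080, 0.900, 0.005),
    REM = c(0.005, 0.030, 0.040, 0.030, 0.000, 0.895)
  )
  colnames(P) <- st
  P
}

#' Default stage-conditioned spectra
#'
#' Oscillation frequency/amplitude and background RMS per stage, in uV
#' at the frontal source, following AASM scoring conventions (alpha near
#' 10 Hz in wake, theta near 5 Hz in N1, slow delta of well over 75 uV
#' peak in N3, low-amplitude mixed-frequency activity in REM).
#'
#' @return Named list per stage.
#' @export
default_stage_spectra <- function() {
  list(
    Art = list(freq = 3.0,  amp = 0,   background = 80),
    W   = list(freq = 10.0, amp = 20,  background = 15),
    N1  = list(freq = 5.0,  amp = 30,  background = 18),
    N2  = list(freq = 2.0,  amp = 15,  background = 25),
    N3  = list(freq = 1.25, amp = 120, background = 30),
    REM = list(freq = 7.0,  amp = 10,  background = 12)
  )
}

#' Source-to-channel mixing of the frontal generator
#'
#' The synthetic night is driven by a single frontal EEG source (the
#' generator of the scored background and of K-complexes/spindles) that
#' projects onto every recorded channel with a channel-specific gain,
#' plus independent white sensor noise. `Fpz` defines the source (gain
#' 1). The ear-electrode gains follow the C-shaped geometry of the grid:
#' the anterior-superior (`R1`, `R2`) and anterior-inferior (`R7`, `R8`)
#' ends of the C face Fpz and see the source with positive sign, while
#' the posterior electrodes (`R4`, `R5`) see the inverted far field of
#' the frontal dipole. This produces the directional correlation
#' topography in which front-pointing bipolar combinations (e.g.
#' `R1-R4`) are maximally positive and rear-pointing ones (e.g.
#' `R5-R8`) negative.
#'
#' @param gain named numeric vector of projection gains for the 11
#'   channels `R1`..`R8`, `Fpz`, `EOG_L`, `EOG_R`; `gain["Fpz"]` must
#'   be 1.
#' @param sensor_noise_sd white sensor-noise standard deviation in uV
#'   (> 0).
#' @return An object of class `source_mixing`.
#' @export
source_mixing <- function(gain = default_source_gain(),
                          sensor_noise_sd = 15) {
  need <- c(paste0("R", 1:8), "Fpz", "EOG_L", "EOG_R")
  if (!all(need %in% names(gain))) {
    stop_earsleep(sprintf("gain must name all channels: %s",
                          paste(need, collapse = ", ")),
                  "earsleep_validation_error")
  }
  if (abs(gain[["Fpz"]] - 1) > 1e-12) {
    stop_earsleep("gain['Fpz'] must equal 1 (source definition)",
                  "earsleep_validation_error")
  }
  if (!is_scalar_number(sensor_noise_sd) || sensor_noise_sd <= 0) {
    stop_earsleep("sensor_noise_sd must be > 0", "earsleep_validation_error")
  }
  structure(list(gain = gain[need], sensor_noise_sd = sensor_noise_sd),
            class = "source_mixing")
}

#' Default frontal-source gain vector
#' @return Named gains for `R1`..`R8`, `Fpz`, `EOG_L`, `EOG_R`.
#' @export
default_source_gain <- function() {
  c(R1 = 0.90, R2 = 0.55, R3 = 0.05, R4 = -0.35,
    R5 = -0.25, R6 = -0.08, R7 = 0.18, R8 = 0.42,
    Fpz = 1.00, EOG_L = 0.30, EOG_R = 0.30)
}

#' Scorer-noise model for an imperfect second rating
#'
#' Emulates inter-rater disagreement: each epoch is independently
#' relabeled with probability `error_prob`, drawing the replacement from
#' the epoch's row of `confusion_kernel` (zero diagonal, biased toward
#' perceptually adjacent stages, e.g. W <-> N1 and N2 <-> N3).
#'
#' @param error_prob per-epoch mislabeling probability in `[0, 1]`.
#' @param confusion_kernel 6 x 6 row-stochastic matrix with zero
#'   diagonal over [sleep_stages()].
#' @param seed default integer seed.
#' @return An object of class `scorer_noise_params`.
#' @export
scorer_noise_params <- function(error_prob = 0.12,
                                confusion_kernel = default_confusion_kernel(),
                                seed = 1L) {
  if (!is_scalar_number(error_prob) || error_prob < 0 || error_prob > 1) {
    stop_earsleep("error_prob must lie in [0, 1]", "earsleep_validation_error")
  }
  st <- sleep_stages()
  K <- confusion_kernel
  if (!is.matrix(K) || !identical(rownames(K), st) ||
      !identical(colnames(K), st) || any(K < 0) ||
      any(abs(rowSums(K) - 1) > 1e-8) || any(abs(diag(K)) > 1e-12)) {
    stop_earsleep(
      "confusion_kernel must be row-stochastic over the stage alphabet with zero diagonal",
      "earsleep_validation_error")
  }
  structure(list(error_prob = error_prob, confusion_kernel = K,
                 seed = as.integer(seed)),
            class = "scorer_noise_params")
}

#' Default mislabel kernel (adjacent-stage biased)
#' @return 6 x 6 row-stochastic matrix with zero diagonal.
#' @export
default_confusion_kernel <- function() {
  st <- sleep_stages()
  K <- rbind(
    Art = c(0.00, 0.50, 0.20, 0.15, 0.05, 0.10),
    W   = c(0.10, 0.00, 0.60, 0.10, 0.02, 0.18),
    N1  = c(0.05, 0.35, 0.00, 0.40, 0.02, 0.18),
    N2  = c(0.03, 0.07, 0.45, 0.00, 0.30, 0.15),
    N3  = c(0.03, 0.02, 0.05, 0.85, 0.00, 0.05),
    REM = c(0.05, 0.25, 0.43, 0.25, 0.02, 0.00)
  )
  colnames(K) <- st
  K
}

#' Simulate a hypnogram as a first-order Markov chain
#'
#' Starts in wake (`W`) and draws each subsequent epoch from the row of
#' the stage-transition matrix belonging to the current stage.
#' Bit-reproducible for a fixed seed.
#'
#' @param params a [sleep_model_params()].
#' @param n_epochs number of 30-s epochs to simulate.
#' @param seed integer seed (default `params$seed`).
#' @return A [hypnogram()].
#' @export
simulate_hypnogram <- function(params, n_epochs, seed = params$seed) {
  stopifnot(inherits(params, "sleep_model_params"))
  P <- validate_transition_matrix(params$stage_transition)
  if (!is_scalar_number(n_epochs) || n_epochs < 1) {
    stop_earsleep("n_epochs must be a positive count",
                  "earsleep_validation_error")
  }
  n_epochs <- as.integer(n_epochs)
  st <- sleep_stages()
  set.seed(seed)
  stages <- character(n_epochs)
  cur <- "W"
  for (i in seq_len(n_epochs)) {
    stages[i] <- cur
    cur <- sample(st, 1L, prob = P[cur, ])
  }
  hypnogram(stages, epoch_length = params$epoch_length)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
}

# Source-level waveforms of the two grapho-elements.
spindle_wave <- function(n, fs, amp) {
  t <- (seq_len(n) - 1L) / fs
  amp * hann_window(n) * sin(2 * pi * 13 * t + stats::runif(1, 0, 2 * pi))
}

k_complex_wave <- function(n, fs, amp) {
  # biphasic transient: sharp negative lobe followed by a slower
  # positive rebound, smoothed by a Hann envelope
  ph <- (seq_len(n) - 1L) / (n - 1L)
  amp * hann_window(n) * (-sin(2 * pi * ph))
}

# AR(1) background ("1/f-like" low-frequency-weighted noise) scaled to a
# target RMS.
ar1_background <- function(n, rms, phi = 0.97) {
  innov_sd <- sqrt(1 - phi^2)
  x <- stats::filter(stats::rnorm(n, sd = innov_sd), phi,
                     method = "recursive")
  as.numeric(x) * rms
}

#' Simulate a multi-channel recording for a given hypnogram
#'
#' Builds the frontal source signal epoch by epoch (stage-conditioned
#' oscillation plus background; K-complexes and sleep spindles placed
#' uniformly and non-overlappingly inside N2 epochs at the configured
#' rates), projects it through the mixing gains onto `R1`..`R8`, `Fpz`,
#' `EOG_L` and `EOG_R`, adds white sensor noise, and overlays
#' opposite-polarity eye-movement deflections on the two EOG channels
#' during REM epochs. Returned annotations carry the true event onsets
#' and durations.
#'
#' @param h a [hypnogram()].
#' @param params a [sleep_model_params()].
#' @param mixing a [source_mixing()].
#' @param seed integer seed (default `params$seed`).
#' @return List with elements `recording` (an [recording()]) and
#'   `events` (annotation data frame as from [read_events()]).
#' @export
simulate_recording <- function(h, params = sleep_model_params(),
                               mixing = source_mixing(),
                               seed = params$seed) {
  stopifnot(inherits(h, "hypnogram"),
            inherits(params, "sleep_model_params"),
            inherits(mixing, "source_mixing"))
  fs <- params$fs
  ep_n <- as.integer(round(h$epoch_length * fs))
  n_ep <- length(h$stages)
  n <- ep_n * n_ep
  set.seed(seed)

  source_sig <- numeric(n)
  eog_move <- numeric(n)   # added to EOG_L, subtracted from EOG_R
  ev_onset <- numeric(0)
  ev_dur <- numeric(0)
  ev_lab <- character(0)

  for (e in seq_len(n_ep)) {
    stage <- h$stages[e]
    spec <- params$stage_spectra[[stage]]
    idx <- ((e - 1L) * ep_n + 1L):(e * ep_n)
    t <- (seq_len(ep_n) - 1L) / fs
    x <- ar1_background(ep_n, spec$background)
    if (spec$amp > 0) {
      x <- x + spec$amp * sin(2 * pi * spec$freq * t +
                                stats::runif(1, 0, 2 * pi))
    }
    if (stage == "N2") {
      placed <- matrix(numeric(0), ncol = 2)  # onset, duration (s, in-epoch)
      for (lab in c("spindle", "k_complex")) {
        rate <- params$event_rates[[lab]]
        if (rate <= 0) next
        n_ev <- stats::rpois(1L, rate * h$epoch_length / 60)
        for (k in seq_len(n_ev)) {
          dur <- if (lab == "spindle") stats::runif(1, 0.5, 2.0)
                 else stats::runif(1, 0.5, 1.0)
          # rejection-sample a non-overlapping in-epoch position
          for (try in 1:20) {
            on <- stats::runif(1, 0, h$epoch_length - dur)
            ok <- nrow(placed) == 0L ||
              all(on + dur <= placed[, 1] | on >= placed[, 1] + placed[, 2])
            if (ok) break
            on <- NA_real_
          }
          if (is.na(on)) next
          placed <- rbind(placed, c(on, dur))
          m <- as.integer(round(dur * fs))
          if (m < 2L) next
          wave <- if (lab == "spindle") {
            spindle_wave(m, fs, params$event_amps[["spindle"]])
          } else {
            k_complex_wave(m, fs, params$event_amps[["k_complex"]])
          }
          at <- as.integer(round(on * fs))
          x[(at + 1L):(at + m)] <- x[(at + 1L):(at + m)] + wave
          ev_onset <- c(ev_onset, (e - 1L) * h$epoch_length + on)
          ev_dur <- c(ev_dur, dur)
          ev_lab <- c(ev_lab, lab)
        }
      }
    }
    if (stage == "REM") {
      # slow, opposite-polarity eye-movement deflections
      n_mov <- stats::rpois(1L, 4 * h$epoch_length / 60)
      mov <- numeric(ep_n)
      for (k in seq_len(n_mov)) {
        dur <- stats::runif(1, 0.3, 1.0)
        on <- stats::runif(1, 0, h$epoch_length - dur)
        m <- as.integer(round(dur * fs))
        if (m < 2L) next
        at <- as.integer(round(on * fs))
        mov[(at + 1L):(at + m)] <- mov[(at + 1L):(at + m)] +
          sample(c(-1, 1), 1L) * 60 * hann_window(m)
      }
      eog_move[idx] <- mov
    }
    source_sig[idx] <- x
  }

  chans <- names(mixing$gain)
  data <- matrix(stats::rnorm(n * length(chans), sd = mixing$sensor_noise_sd),
                 nrow = n, ncol = length(chans))
  colnames(data) <- chans
  for (ch in chans) {
    data[, ch] <- data[, ch] + mixing$gain[[ch]] * source_sig
  }
  data[, "EOG_L"] <- data[, "EOG_L"] + eog_move
  data[, "EOG_R"] <- data[, "EOG_R"] - eog_move

  events <- data.frame(onset_s = ev_onset, duration_s = ev_dur,
                       label = ev_lab,
                       channel = rep("Fpz", length(ev_onset)),
                       stringsAsFactors = FALSE)
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL
  list(recording = recording(data, fs = fs), events = events)
}

#' Corrupt a hypnogram with scorer noise
#'
#' Each epoch is independently relabeled with probability
#' `noise$error_prob`, drawing the new label from the epoch's row of
#' the mislabel kernel. Seed-reproducible.
#'
#' @param h a [hypnogram()].
#' @param noise a [scorer_noise_params()].
#' @param seed integer seed (default `noise$seed`).
#' @return The corrupted [hypnogram()].
#' @export
corrupt_hypnogram <- function(h, noise = scorer_noise_params(),
                              seed = noise$seed) {
  stopifnot(inherits(h, "hypnogram"), inherits(noise, "scorer_noise_params"))
  set.seed(seed)
  st <- sleep_stages()
  out <- h$stages
  flip <- stats::runif(length(out)) < noise$error_prob
  for (i in which(flip)) {
    out[i] <- sample(st, 1L, prob = noise$confusion_kernel[h$stages[i], ])
  }
  hypnogram(out, epoch_length = h$epoch_length)
}

#' Expected kappa under the scorer-noise model
#'
#' Closed-form multi-class Cohen's kappa between a hypnogram with stage
#' frequencies `stage_freqs` and its corruption under
#' [corrupt_hypnogram()]: with mislabel probability `p` and zero-diagonal
#' kernel `K`, observed agreement is `po = 1 - p` and chance agreement
#' `pe = sum_t f_t m_t` where `m = (1 - p) f + p K^T f` is the marginal
#' of the corrupted rating.
#'
#' @param stage_freqs named frequency vector over [sleep_stages()]
#'   (sums to 1), e.g. the empirical stage mix of the clean hypnogram.
#' @param noise a [scorer_noise_params()].
#' @return The expected kappa.
#' @export
expected_corruption_kappa <- function(stage_freqs, noise) {
  stopifnot(inherits(noise, "scorer_noise_params"))
  st <- sleep_stages()
  if (!all(st %in% names(stage_freqs))) {
    stop_earsleep("stage_freqs must name all six stages",
                  "earsleep_validation_error")
  }
  f <- stage_freqs[st]
  if (abs(sum(f) - 1) > 1e-8 || any(f < 0)) {
    stop_earsleep("stage_freqs must be non-negative and sum to 1",
                  "earsleep_validation_error")
  }
  p <- noise$error_prob
  po <- 1 - p
  m <- (1 - p) * f + p * as.vector(t(noise$confusion_kernel) %*% f)
  pe <- sum(f * m)
  (po - pe) / (1 - pe)
}

#' Empirical stage frequencies of a hypnogram
#' @param h a [hypnogram()].
#' @return Named frequency vector over [sleep_stages()] summing to 1.
#' @export
stage_frequencies <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  tab <- table(factor(h$stages, levels = sleep_stages()))
  stats::setNames(as.numeric(tab) / length(h$stages), sleep_stages())
}

#' Write a complete synthetic fixture suite
#'
#' Generates one synthetic night (default 8 h, the order of magnitude of
#' a full home recording), and writes to `outdir`: the recording
#' (`recording.edf`), its true hypnogram (`hypnogram.csv`), the
#' grapho-element annotations (`events.csv`), an imperfect second-scorer
#' hypnogram (`hypnogram_scorer2.csv`), and copies of the three bundled
#' reference confusion matrices.
#'
#' @param outdir writable output directory (created if absent).
#' @param seed integer seed driving every stochastic stage.
#' @param hours length of the synthetic night in hours (default 8).
#' @param params a [sleep_model_params()].
#' @param mixing a [source_mixing()].
#' @param noise a [scorer_noise_params()].
#' @return Named character vector of the written file paths, invisibly.
#' @export
make_fixture_suite <- function(outdir, seed = 1L, hours = 8,
                               params = sleep_model_params(),
                               mixing = source_mixing(),
                               noise = scorer_noise_params()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  n_epochs <- as.integer(round(hours * 3600 / params$epoch_length))
  h <- simulate_hypnogram(params, n_epochs, seed = seed)
  sim <- simulate_recording(h, params, mixing, seed = seed + 1L)
  h2 <- corrupt_hypnogram(h, noise, seed = seed + 2L)
  paths <- c(
    recording = file.path(outdir, "recording.edf"),
    hypnogram = file.path(outdir, "hypnogram.csv"),
    events = file.path(outdir, "events.csv"),
    hypnogram_scorer2 = file.path(outdir, "hypnogram_scorer2.csv"),
    confusion_test_retest = file.path(outdir, "confusion_fpz_test_retest.csv"),
    confusion_vs_ceegrid = file.path(outdir, "confusion_fpz_vs_ceegrid.csv"),
    confusion_vs_ceegrid_eog = file.path(outdir,
                                         "confusion_fpz_vs_ceegrid_eog.csv")
  )
  write_recording(sim$recording, paths[["recording"]], format = "edf")
  write_hypnogram(h, paths[["hypnogram"]])
  write_events(sim$events, paths[["events"]])
  write_hypnogram(h2, paths[["hypnogram_scorer2"]])
  cms <- study_confusion_matrices()
  write_confusion_csv(cms$test_retest, paths[["confusion_test_retest"]])
  write_confusion_csv(cms$fpz_vs_ceegrid, paths[["confusion_vs_ceegrid"]])
  write_confusion_csv(cms$fpz_vs_ceegrid_eog,
                      paths[["confusion_vs_ceegrid_eog"]])
  invisible(paths)
}
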