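# Shared fixture builders. Everything is generated in code; no binary
# files are stored.

ear_labels <- paste0("R", 1:8)
all_channels <- c(ear_labels, "Fpz", "EOG_L", "EOG_R")

# A small deterministic 11-channel recording (sinusoid mixture + noise).
make_test_recording <- function(seconds = 4, fs = 250, seed = 42) {
  set.seed(seed)
  n <- seconds * fs
  t <- (0:(n - 1)) / fs
  data <- sapply(seq_along(all_channels), function(j) {
    sin(2 * pi * (4 + j) * t) * 20 + rnorm(n, sd = 2)
  })
  colnames(data) <- all_channels
  recording(data, fs = fs)
}

# Recording whose channels are exact known signals (no noise), for
# montage arithmetic.
make_unit_recording <- function(values, n = 100, fs = 250) {
  data <- sapply(all_channels, function(ch) {
    rep(if (ch %in% names(values)) values[[ch]] else 0, n)
  })
  colnames(data) <- all_channels
  recording(data, fs = fs)
}

# The three bundled reference confusion matrices, read once per run.
ref_matrices <- study_confusion_matrices()

# Printed per-stage and overall kappa table the fixtures should
# reproduce (rows: stage / "all"; columns: the three test conditions).
printed_kappa_table <- function() {
  data.frame(
    stage = c("W", "N1", "N2", "N3", "REM", "all"),
    test_retest        = c(0.78, 0.46, 0.77, 0.90, 0.86, 0.78),
    fpz_vs_ceegrid     = c(0.71, 0.37, 0.62, 0.85, 0.69, 0.67),
    fpz_vs_ceegrid_eog = c(0.71, 0.42, 0.75, 0.88, 0.83, 0.75),
    stringsAsFactors = FALSE
  )
}
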