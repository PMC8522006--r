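make_epoch_recording <- function(n = 600, fs = 125, seed = 11) {
  set.seed(seed)
  src <- sin(2 * pi * 13 * (0:(n - 1)) / fs) * 30
  data <- sapply(all_channels, function(ch) src + rnorm(n, sd = 5))
  colnames(data) <- all_channels
  recording(data, fs = fs)
}

test_that("epoch extraction windows events and removes DC from every trace", {
  rec <- make_test_recording(seconds = 20, fs = 125)
  ev <- data.frame(onset_s = c(2, 10.5), duration_s = c(1, 1.6),
                   label = c("k_complex", "spindle"), channel = "Fpz",
                   stringsAsFactors = FALSE)
  eps <- extract_epochs(rec, ev)
  expect_length(eps, 2)
  expect_length(eps[[1]]$reference, 125)        # duration * fs
  expect_equal(nrow(eps[[2]]$raw), 200)
  for (ep in eps) {
    expect_equal(mean(ep$reference), 0, tolerance = 1e-10)
    expect_equal(unname(colMeans(ep$raw)), rep(0, 8), tolerance = 1e-10)
  }

  over <- data.frame(onset_s = 19.5, duration_s = 1, label = "spindle",
                     channel = "Fpz", stringsAsFactors = FALSE)
  expect_error(extract_epochs(rec, over), class = "earsleep_bounds_error")
})

test_that("correlations hit +/-1 for identical and inverted traces", {
  n <- 500
  src <- remove_dc(sin(2 * pi * 5 * (0:(n - 1)) / 125))
  raw <- matrix(0, n, 8, dimnames = list(NULL, ear_labels))
  raw[, "R1"] <- src
  raw[, "R2"] <- -src
  ep <- structure(list(event = NULL, reference = src, raw = raw, fs = 125),
                  class = "event_epoch")
  combos <- enumerate_combinations()
  r <- correlate_epoch(ep, combos)
  expect_length(r, 36)
  expect_equal(unname(r[["R1"]]), 1)
  expect_equal(unname(r[["R2"]]), -1)
  # zero-variance combos are missing, never silently 0
  expect_true(is.na(r[["R5"]]))
  expect_true(is.na(r[["R5-R6"]]))
})

test_that("noise at matched variance attenuates r to about 1/sqrt(2)", {
  set.seed(123)
  n <- 4000
  src <- rnorm(n)
  raw <- matrix(0, n, 8, dimnames = list(NULL, ear_labels))
  raw[, "R1"] <- src + rnorm(n, sd = 1)  # SNR 1
  ep <- structure(list(event = NULL, reference = src, raw = raw, fs = 125),
                  class = "event_epoch")
  r <- correlate_epoch(ep, enumerate_combinations()[1])
  expect_equal(unname(r[["R1"]]), 1 / sqrt(2), tolerance = 0.05)
})

test_that("pair correlations agree with the covariance algebra of raw traces", {
  # independent oracle: r(Ri-Rj) from covariances of the raw traces
  set.seed(21)
  n <- 300
  src <- rnorm(n)
  raw <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, ear_labels))
  raw <- raw + outer(src, seq(1, -0.4, length.out = 8))
  ref <- remove_dc(src)
  raw0 <- sweep(raw, 2, colMeans(raw))
  ep <- structure(list(event = NULL, reference = ref, raw = raw0, fs = 125),
                  class = "event_epoch")
  r <- correlate_epoch(ep, enumerate_combinations())
  for (i in 1:7) {
    for (j in (i + 1):8) {
      ci <- stats::cov(ref, raw0[, i]) - stats::cov(ref, raw0[, j])
      vij <- stats::var(raw0[, i]) + stats::var(raw0[, j]) -
        2 * stats::cov(raw0[, i], raw0[, j])
      expected <- ci / sqrt(stats::var(ref) * vij)
      expect_equal(unname(r[[paste0("R", i, "-R", j)]]), expected,
                   tolerance = 1e-12)
    }
  }
})

test_that("Fisher-Z averaging has its fixed point, symmetry and bounds", {
  for (r in c(-0.9, -0.2, 0, 0.5, 0.99)) {
    expect_equal(fisher_average(c(r, r)), r, tolerance = 1e-12)
  }
  expect_equal(fisher_average(c(0.5, 0.9)), 0.766077341597, tolerance = 1e-9)
  expect_equal(fisher_average(c(0.3, -0.3)), 0, tolerance = 1e-12)
  # permutation invariance and range containment on random sets
  set.seed(33)
  for (k in 1:20) {
    rs <- runif(sample(2:10, 1), -0.99, 0.99)
    avg <- fisher_average(rs)
    expect_equal(avg, fisher_average(sample(rs)), tolerance = 1e-12)
    expect_gte(avg, min(rs) - 1e-12)
    expect_lte(avg, max(rs) + 1e-12)
  }
  # +/-1 are clipped, not infinite
  expect_lt(fisher_average(c(1, 1)), 1 + 1e-9)
  expect_error(fisher_average(numeric(0)), class = "earsleep_validation_error")
})

test_that("topography of a single epoch equals that epoch's correlations", {
  rec <- make_epoch_recording()
  ev <- data.frame(onset_s = 1, duration_s = 1.5, label = "spindle",
                   channel = "Fpz", stringsAsFactors = FALSE)
  topo <- topography(rec, ev, "spindle")
  ep <- extract_epochs(rec, ev)[[1]]
  r <- correlate_epoch(ep)
  expect_equal(topo$r_avg, unname(r), tolerance = 1e-12)
  expect_equal(nrow(topo), 36)
  expect_true(all(abs(topo$r_avg) <= 1))

  expect_error(topography(rec, ev, "k_complex"),
               class = "earsleep_validation_error")
})

test_that("grand average over identical participants equals the individual average", {
  rec <- make_epoch_recording()
  ev <- data.frame(onset_s = c(1, 3), duration_s = c(1.5, 1),
                   label = "spindle", channel = "Fpz",
                   stringsAsFactors = FALSE)
  single <- topography(rec, ev, "spindle")
  grand <- topography(list(rec, rec), list(ev, ev), "spindle",
                      grouping = "grand")
  expect_equal(grand$r_avg, single$r_avg, tolerance = 1e-12)
  expect_equal(grand$n_epochs, rep(4, 36))
})
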