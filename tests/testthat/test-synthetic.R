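test_that("hypnogram simulation is seed-reproducible and respects absorbing states", {
  p <- sleep_model_params()
  h1 <- simulate_hypnogram(p, 900, seed = 5)
  h2 <- simulate_hypnogram(p, 900, seed = 5)
  expect_identical(h1$stages, h2$stages)
  expect_false(identical(simulate_hypnogram(p, 900, seed = 6)$stages,
                         h1$stages))

  ident <- diag(6)
  dimnames(ident) <- list(sleep_stages(), sleep_stages())
  p_abs <- sleep_model_params(stage_transition = ident)
  expect_true(all(simulate_hypnogram(p_abs, 50, seed = 1)$stages == "W"))

  bad <- default_stage_transition(); bad[1, 1] <- 2
  expect_error(sleep_model_params(stage_transition = bad),
               class = "earsleep_validation_error")
})

test_that("empirical transition frequencies converge to the matrix rows", {
  p <- sleep_model_params()
  h <- simulate_hypnogram(p, 50000, seed = 8)
  s <- h$stages
  emp <- table(factor(s[-length(s)], levels = sleep_stages()),
               factor(s[-1], levels = sleep_stages()))
  emp <- emp / pmax(rowSums(emp), 1)
  P <- default_stage_transition()
  # rare rows (Art) have few visits; check rows with enough support
  for (st in sleep_stages()) {
    n_st <- sum(s[-length(s)] == st)
    if (n_st >= 500) {
      expect_lt(max(abs(emp[st, ] - P[st, ])), 0.05)
    }
  }
})

test_that("recording simulation returns annotations consistent with the rates", {
  p <- sleep_model_params()
  mix <- source_mixing()
  h_n2 <- hypnogram(rep("N2", 60))  # 30 min of pure N2

  # zero event rates -> no annotations
  p0 <- sleep_model_params(event_rates = c(spindle = 0, k_complex = 0))
  sim0 <- simulate_recording(h_n2, p0, mix, seed = 2)
  expect_equal(nrow(sim0$events), 0)

  # spindle rate 2/min over 30 min -> 60 +/- 16 events (Poisson 2 sigma)
  p2 <- sleep_model_params(event_rates = c(spindle = 2, k_complex = 0))
  sim2 <- simulate_recording(h_n2, p2, mix, seed = 3)
  n_sp <- sum(sim2$events$label == "spindle")
  expect_gte(n_sp, 60 - 16)
  expect_lte(n_sp, 60 + 16)
  # annotations lie inside the recording and inside N2 epochs
  expect_true(all(sim2$events$onset_s >= 0))
  expect_true(all(sim2$events$onset_s + sim2$events$duration_s <= 30 * 60))

  # determinism by seed
  sim2b <- simulate_recording(h_n2, p2, mix, seed = 3)
  expect_identical(sim2$recording$data, sim2b$recording$data)
  expect_identical(sim2$events, sim2b$events)
})

test_that("a zeroed channel gain leaves only the noise floor in correlations", {
  gains <- default_source_gain()
  gains["R1"] <- 0
  mix <- source_mixing(gain = gains)
  p <- sleep_model_params()
  h <- hypnogram(rep("N2", 20))
  sim <- simulate_recording(h, p, mix, seed = 4)
  topo <- topography(downsample(bandpass_filter(sim$recording), 125),
                     sim$events, "spindle")
  r1 <- topo$r_avg[topo$combination == "R1"]
  expect_lt(abs(r1), 0.15)
})

test_that("scorer corruption is seed-stable with identity and chance limits", {
  p <- sleep_model_params()
  h <- simulate_hypnogram(p, 6000, seed = 12)

  clean <- corrupt_hypnogram(h, scorer_noise_params(error_prob = 0), seed = 1)
  expect_identical(clean$stages, h$stages)
  k1 <- cohen_kappa(stage_confusion(align_hypnograms(h, clean)))
  expect_equal(k1$kappa, 1)

  # full corruption through a uniform off-diagonal kernel: observed
  # agreement is exactly 0, so kappa sits slightly below chance at
  # -pe/(1-pe) -- the closed-form expectation of the corruption model
  K <- matrix(1 / 5, 6, 6, dimnames = list(sleep_stages(), sleep_stages()))
  diag(K) <- 0
  noise1 <- scorer_noise_params(error_prob = 1, confusion_kernel = K)
  chaos <- corrupt_hypnogram(h, noise1, seed = 2)
  k0 <- cohen_kappa(stage_confusion(align_hypnograms(h, chaos)))
  expect_equal(k0$po, 0)
  expect_lt(k0$kappa, 0)
  expect_equal(k0$kappa,
               expected_corruption_kappa(stage_frequencies(h), noise1),
               tolerance = 0.05)
})

test_that("measured kappa decreases monotonically with the error probability", {
  p <- sleep_model_params()
  h <- simulate_hypnogram(p, 5000, seed = 14)
  kappas <- sapply(c(0.05, 0.15, 0.3, 0.5, 0.8), function(ep) {
    h2 <- corrupt_hypnogram(h, scorer_noise_params(error_prob = ep),
                            seed = 77)
    cohen_kappa(stage_confusion(align_hypnograms(h, h2)))$kappa
  })
  expect_true(all(diff(kappas) < 0))
})

test_that("measured kappa matches its closed-form expectation", {
  p <- sleep_model_params()
  h <- simulate_hypnogram(p, 10000, seed = 21)
  noise <- scorer_noise_params(error_prob = 0.12)
  h2 <- corrupt_hypnogram(h, noise, seed = 22)
  measured <- cohen_kappa(stage_confusion(align_hypnograms(h, h2)))$kappa
  expected <- expected_corruption_kappa(stage_frequencies(h), noise)
  expect_lt(abs(measured - expected), 0.05)
})

test_that("the fixture suite writes re-readable artifacts", {
  outdir <- withr::local_tempdir()
  paths <- make_fixture_suite(outdir, seed = 31, hours = 0.1)
  expect_true(all(file.exists(paths)))
  rec <- read_recording(paths[["recording"]])
  expect_equal(rec$fs, 250)
  expect_length(rec$channel_labels, 11)
  h <- read_hypnogram(paths[["hypnogram"]])
  expect_length(h, 12)  # 0.1 h of 30-s epochs
  h2 <- read_hypnogram(paths[["hypnogram_scorer2"]])
  expect_length(h2, 12)
  ev <- read_events(paths[["events"]])
  expect_true(all(ev$label %in% c("spindle", "k_complex")))
  cm <- read_confusion_csv(paths[["confusion_test_retest"]])
  expect_equal(sum(cm), 8693)
})

test_that("topography sign pattern follows the gain contrasts", {
  # every combination's averaged r should carry the sign of its gain
  # contrast w . g once epochs are averaged (checked over several seeds)
  gains <- default_source_gain()
  combos <- enumerate_combinations()
  contrast <- vapply(combos, function(d) {
    sum(d$weights * gains[names(d$weights)])
  }, numeric(1))
  p <- sleep_model_params()
  h <- hypnogram(rep("N2", 40))
  hits <- 0
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    sim <- simulate_recording(h, p, source_mixing(), seed = 200 + s)
    topo <- topography(downsample(bandpass_filter(sim$recording), 125),
                       sim$events, "spindle")
    if (all(sign(topo$r_avg) == sign(contrast))) hits <- hits + 1
  }
  expect_gte(hits, n_seeds - 1)
})
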