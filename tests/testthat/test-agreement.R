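test_that("alignment truncates to the common length and honors max_epochs", {
  h1 <- hypnogram(rep(c("W", "N1", "N2"), 300))          # 900 epochs
  h2 <- hypnogram(rep(c("W", "N1", "N2"), length.out = 910))
  expect_equal(nrow(align_hypnograms(h1, h2)), 900)
  # 5 h 20 min of 30-s epochs = 640
  expect_equal(nrow(align_hypnograms(h1, h2, max_epochs = 640)), 640)
  p <- align_hypnograms(h1, h1)
  expect_true(all(p$a == p$b))
  expect_error(align_hypnograms(h1, hypnogram("W", epoch_length = 20)),
               class = "earsleep_validation_error")
})

test_that("stage confusion counts pairs and adds over participants", {
  m <- stage_confusion(rep("N2", 10), rep("N2", 10))
  expect_equal(unname(m["N2", "N2"]), 10L)
  expect_equal(sum(m), 10)

  m2 <- stage_confusion(c("W", "N1"), c("N1", "W"))
  expect_equal(unname(m2["W", "N1"]), 1L)
  expect_equal(unname(m2["N1", "W"]), 1L)
  expect_equal(sum(diag(m2)), 0)

  # concatenation = elementwise sum
  a1 <- c("W", "N2", "N2", "REM"); b1 <- c("W", "N2", "N1", "REM")
  a2 <- c("N3", "N3", "W");        b2 <- c("N3", "N2", "W")
  pooled <- stage_confusion(c(a1, a2), c(b1, b2))
  expect_equal(unclass(pooled),
               unclass(stage_confusion(a1, b1)) +
                 unclass(stage_confusion(a2, b2)))
})

test_that("kappa is 1 on perfect diagonals and 0 on independent margins", {
  d <- diag(c(5, 100, 40, 300, 150, 160))
  dimnames(d) <- list(sleep_stages(), sleep_stages())
  res <- cohen_kappa(d)
  expect_equal(res$kappa, 1)
  expect_equal(res$po, 1)

  # rank-one matrix: counts proportional to products of margins -> po = pe
  rs <- c(2, 10, 4, 30, 15, 16); cs <- c(1, 12, 6, 25, 18, 10)
  m <- outer(rs, cs)
  dimnames(m) <- list(sleep_stages(), sleep_stages())
  expect_equal(cohen_kappa(m)$kappa, 0, tolerance = 1e-12)
})

test_that("kappa is invariant under simultaneous row/column permutation", {
  m <- unclass(ref_matrices$test_retest)
  perm <- c(3, 1, 6, 2, 5, 4)
  mp <- m[perm, perm]
  expect_equal(cohen_kappa(mp)$kappa, cohen_kappa(m)$kappa, tolerance = 1e-12)
})

test_that("one-vs-rest collapse preserves the grand total and perfect agreement", {
  for (st in c("W", "N2", "REM")) {
    res <- one_vs_rest_kappa(ref_matrices$test_retest, st)
    expect_equal(res$n, sum(ref_matrices$test_retest))
  }
  d <- diag(c(5, 100, 40, 300, 150, 160))
  dimnames(d) <- list(sleep_stages(), sleep_stages())
  for (st in sleep_stages()) {
    expect_equal(one_vs_rest_kappa(d, st)$kappa, 1)
  }
})

test_that("kappa of concatenated hypnograms equals kappa of summed matrices", {
  set.seed(17)
  p <- sleep_model_params()
  noise <- scorer_noise_params(error_prob = 0.2)
  hs <- lapply(1:3, function(i) simulate_hypnogram(p, 200, seed = i))
  h2s <- lapply(1:3, function(i) corrupt_hypnogram(hs[[i]], noise,
                                                   seed = 100 + i))
  pooled_pairs <- align_hypnograms(concatenate_hypnograms(hs),
                                   concatenate_hypnograms(h2s))
  k_concat <- cohen_kappa(stage_confusion(pooled_pairs))$kappa
  summed <- Reduce(`+`, Map(function(h, h2) {
    unclass(stage_confusion(align_hypnograms(h, h2)))
  }, hs, h2s))
  dimnames(summed) <- list(sleep_stages(), sleep_stages())
  expect_equal(cohen_kappa(summed)$kappa, k_concat, tolerance = 1e-12)
})

test_that("the standard error scales as 1/sqrt(count scale)", {
  m <- unclass(ref_matrices$test_retest)
  se1 <- cohen_kappa(m)$se
  se4 <- cohen_kappa(m * 4L)$se
  expect_equal(se4, se1 / 2, tolerance = 0.01)
  # printed SEs are of order 0.01
  expect_gt(se1, 1e-4)
  expect_lt(se1, 0.05)
})

test_that("Landis-Koch labels follow the conventional bands", {
  expect_equal(landis_koch_label(-0.2), "poor")
  expect_equal(landis_koch_label(0), "poor")
  expect_equal(landis_koch_label(0.1), "slight")
  expect_equal(landis_koch_label(0.2), "slight")
  expect_equal(landis_koch_label(0.37), "fair")
  expect_equal(landis_koch_label(0.46), "moderate")
  expect_equal(landis_koch_label(0.67), "substantial")
  expect_equal(landis_koch_label(0.8), "substantial")
  expect_equal(landis_koch_label(0.9), "almost perfect")
  expect_equal(landis_koch_label(1), "almost perfect")
  expect_error(landis_koch_label(1.2), class = "earsleep_validation_error")
})

test_that("paired one-tailed t-test behaves across regimes", {
  a <- c(0.60, 0.72, 0.55, 0.68, 0.64)
  # identical inputs: no-effect limit
  expect_equal(paired_t_onetailed(a, a)$p, 0.5)
  # constant nonzero difference: degenerate
  expect_error(paired_t_onetailed(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4)),
               class = "earsleep_degenerate_test_error")
  # growing shift drives p toward 0 monotonically
  set.seed(2)
  jitter <- rnorm(5, sd = 0.01)
  ps <- sapply(c(0.01, 0.05, 0.1), function(delta) {
    paired_t_onetailed(a, a + delta + jitter)$p
  })
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[3], 0.01)
  # matches the textbook paired t computed by hand
  b <- a + c(0.08, 0.02, 0.05, 0.09, 0.01)
  res <- paired_t_onetailed(a, b)
  d <- b - a
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p, stats::pt(t_manual, length(d) - 1, lower.tail = FALSE),
               tolerance = 1e-12)
})
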