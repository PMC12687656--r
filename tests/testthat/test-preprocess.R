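test_that("envelope rejects DC, recovers sinusoid rectified mean and AM modulators", {
  # constant input: high-pass removes it entirely
  env <- emg_envelope(flat_emg(rep(2, 1200)))
  expect_lt(max(abs(env$signal)), 1e-6 * 2)

  # 100 Hz unit sinusoid at 600 Hz: envelope ~ mean(|sin|) = 2/pi
  tt <- (0:1199) / 600
  env <- emg_envelope(flat_emg(sin(2 * pi * 100 * tt + 0.7)))
  interior <- env$signal[1, 201:1000]
  expect_lt(abs(mean(interior) - 2 / pi) / (2 / pi), 0.05)

  # white noise amplitude-modulated by a known bump
  set.seed(11)
  bump <- exp(-((0:2399) / 600 - 2)^2 / (2 * 0.3^2))
  x <- matrix(rnorm(8 * 2400), 8) * rep(bump, each = 8)
  env <- emg_envelope(emg_trial(x, 600))
  for (i in 1:8) expect_gt(cor(env$signal[i, ], bump), 0.9)

  expect_error(emg_envelope(flat_emg(rnorm(100), rate_hz = 70)), "Nyquist")
})

test_that("window selects BON-100ms to TD+100ms and validates its bounds", {
  tr <- flat_emg(seq_len(1200) / 1200)
  w <- window_trial(tr, list(bon_s = 1.0, td_s = 1.28))
  expect_equal(ncol(w$signal), 288)   # 0.48 s at 600 Hz
  # start inclusive: first sample is the one at 0.9 s
  expect_equal(w$signal[1, 1], tr$signal[1, 541])

  expect_error(window_trial(tr, list(bon_s = 1.0, td_s = 1.0)), "after belt onset")
  expect_error(window_trial(tr, list(bon_s = 0.05, td_s = 0.5)), "before the trial")
  expect_error(window_trial(tr, list(bon_s = 1.0, td_s = 2.5)), "past the trial")
})

test_that("bin averaging partitions samples and drops the trailing partial bin", {
  tr <- flat_emg(rep(0.5, 288))
  m <- bin_average(tr, 10)
  expect_equal(ncol(m$values), 48)
  expect_true(all(abs(m$values - 0.5) < 1e-12))

  m6 <- bin_average(flat_emg(c(0, 6, 0, 6, 6, 6)), 10)
  expect_equal(unname(m6$values[1, 1]), 4.0)

  # 605 samples at 600 Hz -> 100 full bins, 5 trailing samples dropped
  m2 <- bin_average(flat_emg(rep(1, 605)), 10)
  expect_equal(ncol(m2$values), 100)

  expect_error(bin_average(flat_emg(c(1, 1)), 10), "shorter than one bin")

  # binning commutes with scaling by a constant
  set.seed(5)
  x <- abs(rnorm(300))
  expect_equal(bin_average(flat_emg(3 * x), 10)$values,
               3 * bin_average(flat_emg(x), 10)$values, tolerance = 1e-12)
})

test_that("concatenation appends trial blocks and records 1-based boundaries", {
  a <- make_env(matrix(1, 8, 48))
  b <- make_env(matrix(2, 8, 52))
  m <- concatenate_envelopes(list(a, b))
  expect_equal(ncol(m$values), 100)
  expect_equal(m$trial_boundaries, c(1L, 49L))

  single <- concatenate_envelopes(list(a))
  expect_equal(single$values, a$values)
  expect_equal(single$trial_boundaries, 1L)

  swapped <- concatenate_envelopes(list(b, a))
  expect_equal(swapped$values[, 1:52], m$values[, 49:100])
  expect_equal(swapped$values[, 53:100], m$values[, 1:48])

  expect_error(concatenate_envelopes(list(a, make_env(matrix(1, 8, 10), bin_ms = 20))),
               "bin widths")
})

test_that("max normalization and unit-variance scaling store their factors", {
  set.seed(6)
  vals <- matrix(abs(rnorm(8 * 50)), 8)
  m <- make_env(vals)
  n1 <- normalize_max(m)
  expect_equal(unname(apply(n1$values, 1, max)), rep(1, 8))
  expect_equal(n1$norm_factors, unname(apply(vals, 1, max)))

  # shared session factors can leave a block's maxima below 1
  shared <- normalize_max(m, norm_factors = apply(vals, 1, max) * 2)
  expect_true(all(apply(shared$values, 1, max) <= 1))
  expect_true(any(apply(shared$values, 1, max) < 1))

  zero <- vals; zero[3, ] <- 0
  expect_error(normalize_max(make_env(zero)), "R_VLAT")

  s1 <- scale_unit_variance(n1)
  expect_equal(unname(apply(s1$values, 1, sd)), rep(1, 8), tolerance = 1e-9)
  expect_equal(s1$unit_var_scales, unname(apply(n1$values, 1, sd)))
  expect_error(scale_unit_variance(make_env(matrix(1, 8, 10))), "zero-variance")
})

test_that("the preprocessing chain output is non-negative with negligible clipping", {
  gt <- make_ground_truth()
  s <- make_synthetic_session("P01", gt, n_trials = 1, seed = 21)
  env <- emg_envelope(s$trials[[1]]$emg)
  expect_true(all(env$signal >= 0))
  expect_lt(attr(env, "clipped_mass"), 0.01)
})

test_that("normalize-then-scale differs from scale-then-normalize", {
  set.seed(7)
  m <- make_env(matrix(abs(rnorm(8 * 60)) + 0.1, 8))
  a <- scale_unit_variance(normalize_max(m))          # the pipeline order
  b <- normalize_max(scale_unit_variance(m))
  expect_gt(max(abs(a$values - b$values)), 0.01)
})
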