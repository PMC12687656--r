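test_that("belt profiles integrate to their commanded displacement", {
  for (p in list(c(0.18, 0.45, 11.35), c(0.14, 0.36, 9))) {
    bp <- make_belt_profile(p[1], p[2], p[3], rate_hz = 120)
    expect_equal(bp$t_acc, p[2] / p[3], tolerance = 1e-12)
    trapz <- sum((bp$velocity[-1] + bp$velocity[-length(bp$velocity)]) / 2) /
      bp$rate_hz
    expect_lt(abs(trapz - p[1]), 1e-3)
    expect_equal(bp$position[length(bp$position)], p[1], tolerance = 1e-9)
  }
  # displacement too short for the trapezoid
  expect_error(make_belt_profile(0.01, 0.45, 11.35), "triangular")
})

test_that("ground truth templates are distinct, seeded and stance-slip-shaped", {
  gt <- make_ground_truth()
  expect_equal(colnames(gt$W_true)[3], "W_R_GAS")
  expect_equal(canonical_channels()[which.max(gt$W_true[, 3])], "R_GAS")
  expect_equal(unname(apply(gt$W_true, 2, max)), rep(1, 5))

  gr1 <- make_ground_truth(k = 4, template = "random", seed = 7)
  gr2 <- make_ground_truth(k = 4, template = "random", seed = 7)
  expect_identical(gr1$W_true, gr2$W_true)
  Wn <- sweep(gr1$W_true, 2, sqrt(colSums(gr1$W_true^2)), "/")
  cs <- crossprod(Wn)
  expect_true(all(cs[upper.tri(cs)] < 0.95))
  expect_error(make_ground_truth(k = 4, template = "fig4_like"), "exactly 5")
})

test_that("synthetic EMG is seed-deterministic and its envelope carries W C", {
  gt <- make_ground_truth(noise_sd = 0)
  sc <- list(bon_s = 2, td_s = 2.43, id = "t", stage = "early")
  e1 <- synthesize_emg(gt$W_true, gt$C_params, sc, noise_sd = 0, seed = 5)
  e2 <- synthesize_emg(gt$W_true, gt$C_params, sc, noise_sd = 0, seed = 5)
  expect_identical(e1$signal, e2$signal)

  # preprocessing recovers the planted envelope up to scale
  env <- bin_average(window_trial(emg_envelope(e1), list(bon_s = 2, td_s = 2.43)))
  nb <- ncol(env$values)
  pct <- seq(0, 100, length.out = nb)
  planted <- gt$W_true %*%
    t(vapply(seq_len(5), function(i) {
      gt$C_params$amplitude[i] *
        exp(-(pct - gt$C_params$peak_time_pct[i])^2 / (2 * 25)) + 0.02
    }, numeric(nb)))
  for (i in 1:8) expect_gt(cor(env$values[i, ], planted[i, ]), 0.98)

  # linearity: doubling the planted amplitude doubles the recovered envelope
  e3 <- synthesize_emg(2 * gt$W_true, gt$C_params, sc, noise_sd = 0, seed = 5)
  env3 <- bin_average(window_trial(emg_envelope(e3), list(bon_s = 2, td_s = 2.43)))
  ratio <- mean(env3$values) / mean(env$values)
  expect_lt(abs(ratio - 2) / 2, 0.05)
})

test_that("synthetic sessions script events consistently and reproduce bytes", {
  gt <- make_ground_truth()
  expect_error(make_synthetic_session("P", gt, seed = 1,
                                      kin_shift = list(initiation_s = -5,
                                                       step_length_m = 0)),
               NA)   # shifts are clamped, not fatal
  s1 <- make_synthetic_session("P01", gt, n_trials = 3, seed = 31)
  s2 <- make_synthetic_session("P01", gt, n_trials = 3, seed = 31)
  expect_identical(s1$trials[[2]]$emg$signal, s2$trials[[2]]$emg$signal)
  expect_identical(s1$trials[[3]]$markers$positions, s2$trials[[3]]$markers$positions)
  tru <- attr(s1, "ground_truth")
  for (sc in tru$scripts) expect_true(sc$bon_s < sc$liftoff_s && sc$liftoff_s < sc$td_s)
  expect_error(synthesize_markers(list(bon_s = 3, liftoff_s = 2.5, td_s = 3.2,
                                       step_length_m = 0.2)),
               "ordering")
  expect_error(make_cohort(n = 2), "at least 3")
})

test_that("script-level cohorts plant the requested reweighting", {
  # a reduction on a non-dominant muscle survives unit-max normalization;
  # recovery BFLH within the recovery-GAS mode is the canonical example
  rw <- list(mode = 3, muscle = "R_BFLH", delta = -0.2, sd = 0.05)
  co <- make_cohort(n = 40, reweight = rw, signals = FALSE, seed = 9)
  d <- vapply(co, function(tr) {
    tr$W_late["R_BFLH", 3] - tr$W_early["R_BFLH", 3]
  }, 1)
  expect_lt(mean(d), -0.1)    # reduction present on average
  co0 <- make_cohort(n = 40, signals = FALSE, seed = 9)
  d0 <- vapply(co0, function(tr) tr$W_late["R_BFLH", 3] - tr$W_early["R_BFLH", 3], 1)
  expect_lt(abs(mean(d0)), 0.05)   # and absent under the null
})
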