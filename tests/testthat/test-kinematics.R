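test_that("marker low-pass preserves slow components and kills fast ones", {
  n <- 480; tt <- (0:(n - 1)) / 120
  pos <- base_posture()
  m <- static_markers(pos, n_frames = n)
  m$positions["R_HEEL", , 1] <- sin(2 * pi * 1 * tt)        # 1 Hz
  m$positions["L_HEEL", , 1] <- sin(2 * pi * 30 * tt)       # 30 Hz
  mf <- lowpass_markers(m, 6)
  # constant trajectory untouched
  expect_lt(max(abs(marker_xyz(mf, "R_HIP")[, 3] - pos$R_HIP[3])), 1e-9)
  # 1 Hz passband within 1%
  mid <- 100:380
  expect_lt(abs(max(abs(marker_xyz(mf, "R_HEEL")[mid, 1])) - 1), 0.01)
  # 30 Hz attenuated > 90%
  expect_lt(max(abs(marker_xyz(mf, "L_HEEL")[mid, 1])), 0.1)
  expect_error(lowpass_markers(m, 60), "Nyquist")
})

test_that("belt onset detection matches the trapezoid profile start", {
  pos <- base_posture()
  n <- 600
  m <- static_markers(pos, n_frames = n)
  belt <- make_belt_profile()
  tt <- (0:(n - 1)) / 120
  bon <- 2.0
  idx <- findInterval(tt - bon, belt$time)
  disp <- ifelse(tt < bon, 0, ifelse(idx >= length(belt$time),
                                     belt$displacement_m, belt$position[pmax(idx, 1)]))
  m$positions["BELT", , 1] <- pos$BELT[1] + disp
  expect_lt(abs(detect_bon(m) - bon), 2 / 120)   # crossing lands within a frame or two of motion start

  # stationary belt
  expect_error(detect_bon(static_markers(pos, 100)), "never exceeds")

  # a single-frame spike is not belt onset
  m2 <- static_markers(pos, n_frames = n)
  m2$positions["BELT", 240, 1] <- pos$BELT[1] + 0.05
  expect_error(detect_bon(m2), "never exceeds")
})

test_that("liftoff/touchdown bracket a scripted minimum-jerk step", {
  pos <- base_posture()
  n <- 720; tt <- (0:(n - 1)) / 120
  m <- static_markers(pos, n_frames = n)
  lo <- 3.0; td <- 3.17; L <- 0.2
  u <- pmin(pmax((tt - lo) / (td - lo), 0), 1)
  s <- 10 * u^3 - 15 * u^4 + 6 * u^5
  m$positions["R_HEEL", , 1] <- pos$R_HEEL[1] - L * s
  ev <- detect_step_events(m, "R_HEEL", bon_s = 2.8)
  expect_lt(abs(ev$liftoff_s - lo), 1 / 120)
  expect_lt(abs(ev$td_s - td), 1 / 120)

  expect_error(detect_step_events(static_markers(pos, 200), "R_HEEL", 0.5),
               "no heel liftoff")
})

test_that("step metrics implement the touchdown geometry definitions", {
  pos <- base_posture()
  pos$R_HEEL <- c(0.30, -0.105, 0.02)   # recovery heel behind after backward step?
  pos$L_HEEL <- c(0.50, 0.105, 0.02)
  m <- static_markers(pos, n_frames = 120)
  ev <- structure(list(bon_s = 0.2, liftoff_s = 0.45, td_s = 0.63,
                       recovery_side = "right"), class = "trial_events")
  sm <- step_metrics(m, ev)
  expect_equal(sm$step_initiation_s, 0.25)
  expect_equal(sm$step_execution_s, 0.18, tolerance = 1e-12)
  expect_equal(unname(sm$step_length_m), 0.20, tolerance = 1e-12)
  expect_equal(unname(sm$step_width_m), 0.21, tolerance = 1e-12)
})

test_that("segmental COM estimation follows the parameter table", {
  # single full-mass segment: COM at the segment midpoint
  tab1 <- data.frame(segment = "rod", proximal = "L_HIP", distal = "R_HIP",
                     mass_fraction = 1, com_fraction = 0.5)
  pos <- base_posture()
  m <- static_markers(pos, n_frames = 10)
  com <- com_estimate(m, tab1)
  expect_equal(com[1, ], c(X = 0, Y = 0, Z = 0.9), tolerance = 1e-12)

  # two equal point masses at x = 0 and x = 1
  pos2 <- pos; pos2$L_HIP[1] <- 0; pos2$R_HIP[1] <- 1
  tab2 <- data.frame(segment = c("a", "b"),
                     proximal = c("L_HIP", "R_HIP"), distal = c("L_HIP", "R_HIP"),
                     mass_fraction = c(0.5, 0.5), com_fraction = 0)
  expect_equal(unname(com_estimate(static_markers(pos2, 5), tab2)[1, 1]), 0.5)

  bad <- tab2; bad$mass_fraction <- c(0.5, 0.4)
  expect_error(com_estimate(m, bad), "sum to 1")
  missing <- tab2; missing$proximal[1] <- "STERNUM"
  expect_error(com_estimate(m, missing), "STERNUM")

  # default table masses are a valid partition
  expect_equal(sum(default_segment_table()$mass_fraction), 1, tolerance = 1e-9)

  # generator self-consistency: noiseless markers reproduce the generator COM
  gt <- make_ground_truth()
  sc <- list(bon_s = 2, liftoff_s = 2.25, td_s = 2.43, step_length_m = 0.2)
  out <- synthesize_markers(sc, noise_sd_m = 0, seed = 1)
  expect_lt(max(abs(com_estimate(out$markers) - out$com_true)), 1e-9)
})

test_that("COM state normalizes by the base of support at touchdown", {
  pos <- base_posture()
  pos$R_HEEL <- c(0, -0.1, 0.02); pos$L_HEEL <- c(0.1, 0.1, 0.02)
  pos$R_TOE <- c(0.25, -0.15, 0.02); pos$L_TOE <- c(0.35, 0.15, 0.02)
  m <- static_markers(pos, 60)
  ev <- structure(list(bon_s = 0.1, liftoff_s = 0.2, td_s = 0.3,
                       recovery_side = "right"), class = "trial_events")
  # a static COM exactly at the recovery heel -> ap 0; centered -> ml 0.5
  com <- matrix(rep(c(0, 0, 1), each = 60), 60)
  cs <- com_state(com, m, ev)
  expect_equal(unname(cs$ap_com_pos_norm), 0)
  expect_equal(unname(cs$ml_com_pos_norm), 0.5)   # BOS edges at +-0.15, width 0.3
  expect_equal(cs$ap_com_vel_mps, 0)
  expect_equal(cs$ml_com_vel_mps, 0)

  # moving COM against a moving recovery heel: velocities subtract
  tt <- (0:59) / 120
  com2 <- cbind(0.5 * tt, 0, 1)
  m2 <- m
  m2$positions["R_HEEL", , 1] <- 0.2 * tt
  cs2 <- com_state(com2, m2, ev)
  expect_equal(cs2$ap_com_vel_mps, 0.3, tolerance = 1e-9)
})

test_that("trunk and arm angles follow the sagittal conventions", {
  pos <- base_posture()
  m <- static_markers(pos, 60)
  ev <- structure(list(bon_s = 0.1, liftoff_s = 0.2, td_s = 0.3,
                       recovery_side = "right"), class = "trial_events")
  ta <- trunk_arm_angles(m, ev)
  expect_equal(ta$trunk_angle_deg, 90)           # shoulders above hips
  expect_equal(ta$arm_flexion_deg, 0, tolerance = 1e-9)  # arms straight down

  # shoulder midpoint moved forward so the trunk makes 45 deg with horizontal
  pos45 <- pos
  dz <- 0.5
  pos45$L_SHOULDER <- c(dz, 0.18, 0.9 + dz); pos45$R_SHOULDER <- c(dz, -0.18, 0.9 + dz)
  ta45 <- trunk_arm_angles(static_markers(pos45, 60), ev)
  expect_equal(ta45$trunk_angle_deg, 45, tolerance = 1e-9)

  # one arm flexed forward 30 degrees: the larger angle is reported
  pos30 <- pos
  len <- 0.3
  pos30$R_ELBOW <- c(pos$R_SHOULDER[1] + len * sin(pi / 6), -0.2,
                     pos$R_SHOULDER[3] - len * cos(pi / 6))
  ta30 <- trunk_arm_angles(static_markers(pos30, 60), ev)
  expect_equal(ta30$arm_flexion_deg, 30, tolerance = 1e-6)
})

test_that("fall classification applies the strict 30% body-weight rule", {
  bw <- 700
  mk <- function(peak) loadcell_trial(c(rep(0, 10), peak * bw, rep(0, 10)), 600, bw)
  expect_true(detect_fall(mk(0.31)))
  expect_false(detect_fall(mk(0.29)))
  expect_false(detect_fall(mk(0.30)))   # boundary: strictly greater only
})

test_that("scripted kinematics are recovered end-to-end within tolerance", {
  gt <- make_ground_truth()
  cfg <- pipeline_config()
  frame_errs <- c(); len_errs <- c()
  for (seed in 1:8) {
    s <- make_synthetic_session(sprintf("P%02d", seed), gt, n_trials = 2, seed = seed)
    tru <- attr(s, "ground_truth")
    for (i in 1:2) {
      tr <- s$trials[[i]]; sc <- tru$scripts[[i]]
      kin <- trial_kinematics(tr$markers, tr$loadcell, "right", cfg)
      frame_errs <- c(frame_errs,
                      (kin$bon_s - sc$bon_s) * 120,
                      (kin$liftoff_s - sc$liftoff_s) * 120,
                      (kin$td_s - sc$td_s) * 120)
      len_errs <- c(len_errs, (kin$step_length_m - sc$step_length_m) * 1000)
      expect_true(kin$bon_s < kin$liftoff_s && kin$liftoff_s < kin$td_s)
      expect_gt(kin$step_length_m, 0)   # backward steps have positive length
      expect_false(kin$fall)
    }
  }
  expect_lt(mean(abs(frame_errs)), 2)
  expect_lt(mean(abs(len_errs)), 2)
})
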