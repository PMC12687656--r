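#' Trapezoidal treadmill belt profile
#'
#' Three-phase belt velocity profile: constant acceleration to peak
#' velocity, a constant-speed phase, and a symmetric deceleration, sized so
#' the belt travels exactly the commanded displacement. The training
#' protocol uses displacement 0.18 m, velocity 0.45 m/s and acceleration
#' 11.35 m/s^2 (familiarization: 0.14 m, 0.36 m/s, 9 m/s^2).
#'
#' @param displacement_m Total belt travel, metres.
#' @param velocity_mps Peak belt velocity, m/s.
#' @param accel_mps2 Belt acceleration (deceleration magnitude equals it).
#' @param rate_hz Sampling rate for the returned traces.
#' @return Object of class `belt_profile`: phase durations `t_acc`,
#'   `t_const`, `t_dec`, total `duration_s`, and sampled `time`,
#'   `velocity`, `position` traces (positions analytic, not integrated
#'   numerically).
#' @export
make_belt_profile <- function(displacement_m = 0.18, velocity_mps = 0.45,
                              accel_mps2 = 11.35, rate_hz = 120) {
  if (displacement_m <= velocity_mps^2 / accel_mps2) {
    stop("displacement too short to reach peak velocity; use a triangular profile")
  }
  t_acc <- velocity_mps / accel_mps2
  t_const <- (displacement_m - velocity_mps^2 / accel_mps2) / velocity_mps
  t_dec <- t_acc
  duration <- t_acc + t_const + t_dec
  tt <- seq(0, ceiling(duration * rate_hz) / rate_hz, by = 1 / rate_hz)
  vel <- ifelse(tt < t_acc, accel_mps2 * tt,
         ifelse(tt < t_acc + t_const, velocity_mps,
                pmax(velocity_mps - accel_mps2 * (tt - t_acc - t_const), 0)))
  pos <- ifelse(tt < t_acc, 0.5 * accel_mps2 * tt^2,
         ifelse(tt < t_acc + t_const,
                0.5 * velocity_mps * t_acc + velocity_mps * (tt - t_acc),
                displacement_m - 0.5 * accel_mps2 * pmax(duration - tt, 0)^2))
  structure(list(displacement_m = displacement_m, peak_velocity_mps = velocity_mps,
                 accel_mps2 = accel_mps2, t_acc = t_acc, t_const = t_const,
                 t_dec = t_dec, duration_s = duration, rate_hz = rate_hz,
                 time = tt, velocity = vel, position = pos),
            class = "belt_profile")
}

#' @export
print.belt_profile <- function(x, ...) {
  cat(sprintf("<belt_profile> %.2f m at %.2f m/s, %.2f m/s^2 (phases %.3f/%.3f/%.3f s)\n",
              x$displacement_m, x$peak_velocity_mps, x$accel_mps2,
              x$t_acc, x$t_const, x$t_dec))
  invisible(x)
}

# Fixed synergy template mirroring the five modes observed in stance-slip
# responses, in activation-peak order: a bilateral TA mode, then slipping
# VLAT, recovery GAS, recovery VLAT, slipping GAS dominant modes. Dominant
# weight 1, sub-dominant weights at most 0.6.
fig4_template <- function() {
  W <- cbind(
    W_TA     = c(1.00, 0.05, 0.15, 0.25, 0.97, 0.05, 0.15, 0.20),
    W_S_VLAT = c(0.10, 0.05, 0.20, 0.10, 0.20, 0.10, 1.00, 0.45),
    W_R_GAS  = c(0.05, 1.00, 0.10, 0.50, 0.05, 0.15, 0.30, 0.10),
    W_R_VLAT = c(0.20, 0.10, 1.00, 0.30, 0.10, 0.05, 0.20, 0.10),
    W_S_GAS  = c(0.05, 0.20, 0.10, 0.10, 0.10, 1.00, 0.15, 0.40))
  rownames(W) <- canonical_channels()
  W
}

#' Ground truth for a synthetic participant cohort
#'
#' Defines the planted synergy vectors, the Gaussian-bump activation
#' parameters, the envelope noise level, and (optionally) the late-stage
#' reweighting applied to individual muscle weights — everything the
#' pipeline is later asked to recover.
#'
#' @param k Number of planted synergies (fixed at 5 for `fig4_like`).
#' @param template `"fig4_like"` (the fixed five-mode stance-slip template)
#'   or `"random"` (unit-max uniform weights, pairwise cosine < 0.95 by
#'   rejection).
#' @param noise_sd Envelope noise standard deviation as a fraction of the
#'   mean windowed signal (default 0.10).
#' @param seed Integer seed (used by the `random` template).
#' @return Object of class `ground_truth`: `W_true` (8 x k, unit max),
#'   `C_params` (per-synergy `peak_time_pct`, `width_pct`, `amplitude`),
#'   `noise_sd`, `seed`.
#' @export
make_ground_truth <- function(k = 5, template = c("fig4_like", "random"),
                              noise_sd = 0.10, seed = 1L) {
  template <- match.arg(template)
  if (template == "fig4_like") {
    if (k != 5) stop("the fig4_like template has exactly 5 modes")
    W <- fig4_template()
  } else {
    set.seed(seed)
    for (attempt in 1:1000) {
      W <- matrix(stats::runif(8 * k), 8, k)
      W <- sweep(W, 2, apply(W, 2, max), "/")
      cs <- crossprod(W / sqrt(colSums(W^2)))
      if (all(cs[upper.tri(cs)] < 0.95)) break
      if (attempt == 1000) stop("could not draw sufficiently distinct synergy vectors")
    }
    rownames(W) <- canonical_channels()
    colnames(W) <- paste0("syn", seq_len(k))
  }
  C_params <- data.frame(
    synergy = colnames(W),
    peak_time_pct = seq(20, 80, length.out = k),
    width_pct = 5,
    amplitude = rep(c(1.0, 0.9, 1.0, 0.8, 0.9), length.out = k))
  structure(list(W_true = W, C_params = C_params, noise_sd = noise_sd,
                 template = template, seed = as.integer(seed)),
            class = "ground_truth")
}

# Gaussian-bump activation curves evaluated at window positions pct (0-100).
activation_bumps <- function(C_params, pct, baseline = 0.02) {
  t(vapply(seq_len(nrow(C_params)), function(i) {
    C_params$amplitude[i] *
      exp(-(pct - C_params$peak_time_pct[i])^2 / (2 * C_params$width_pct[i]^2)) +
      baseline
  }, numeric(length(pct))))
}

#' Synthesize one trial of raw multi-channel EMG
#'
#' Builds the planted envelope E(t) = W C(t) (Gaussian-bump activations
#' inside the analysis window, resting baseline outside), adds truncated
#' Gaussian envelope noise, and emits the raw signal as the envelope
#' modulating a zero-mean broadband carrier (white noise band-passed
#' 35-250 Hz, flattened to near-constant modulus, unit variance), so the
#' envelope-extraction chain is genuinely exercised and recovers E up to a
#' constant scale.
#'
#' @param W Participant synergy matrix (8 x k, unit max).
#' @param C_params Activation bump parameters (see [make_ground_truth()]).
#' @param script Trial script: `bon_s`, `td_s` (seconds).
#' @param noise_sd Envelope noise sd, fraction of the mean window signal.
#' @param rate_hz EMG sampling rate (default 600).
#' @param duration_s Trial length, seconds (default 8, the protocol trial).
#' @param pre_ms,post_ms Analysis window margins.
#' @param seed Integer seed.
#' @return An [emg_trial()] of raw EMG.
#' @export
synthesize_emg <- function(W, C_params, script, noise_sd = 0.10,
                           rate_hz = 600, duration_s = 8,
                           pre_ms = 100, post_ms = 100, seed = 1L) {
  set.seed(seed)
  n <- round(duration_s * rate_hz)
  tt <- (seq_len(n) - 1) / rate_hz
  w0 <- script$bon_s - pre_ms / 1000
  w1 <- script$td_s + post_ms / 1000
  pct <- (tt - w0) / (w1 - w0) * 100
  Cfull <- activation_bumps(C_params, pct)
  Cfull[, pct < 0 | pct > 100] <- 0.02     # resting baseline outside the window
  E <- W %*% Cfull
  # post-touchdown stabilization burst: the hamstrings peak while arresting
  # the trunk after the recovery step, outside the analysis window, so their
  # whole-trial maxima exceed their in-window synergy contributions
  burst <- stabilization_burst_amp() *
    exp(-(tt - (script$td_s + 0.6))^2 / (2 * 0.15^2))
  E[c("R_BFLH", "S_BFLH"), ] <- sweep(E[c("R_BFLH", "S_BFLH"), ], 2, burst, "+")
  if (noise_sd > 0) {
    scale <- noise_sd * mean(E[, pct >= 0 & pct <= 100])
    E <- pmax(E + matrix(stats::rnorm(length(E), 0, scale), nrow(E)), 0)
  }
  # broadband carrier flattened to (near) constant modulus: dividing the
  # band-passed noise by its own smoothed rectified envelope removes the
  # Rayleigh amplitude fluctuation, so the emitted signal's envelope is the
  # planted E(t) rather than E(t) times carrier amplitude noise
  bp <- signal::butter(2, c(35, 250) / (rate_hz / 2), type = "pass")
  lp <- signal::butter(2, 40 / (rate_hz / 2), type = "low")
  carrier <- t(apply(matrix(stats::rnorm(8 * n), 8, n), 1, function(x) {
    y <- filtfilt_pad(bp, x)
    amp <- filtfilt_pad(lp, abs(y))
    y <- y / pmax(amp, 0.1 * mean(abs(y)))
    y / stats::sd(y)
  }))
  emg_trial(E * carrier, rate_hz, trial_id = script$id %||% "sim",
            stage = script$stage %||% "other")
}

stabilization_burst_amp <- function() 0.8

#' Analysis-space planted synergy vectors
#'
#' The pipeline reports synergy weights in max-normalized units: each
#' muscle\'s envelope is divided by its whole-trial maximum before
#' extraction. The planted weights expressed in those units are
#' `W[m,k] * amplitude[k] / norm_m`, where `norm_m` is the muscle\'s
#' noise-free whole-trial envelope maximum (including the hamstring
#' stabilization burst), followed by unit-max column scaling. Use this as
#' the ground truth when comparing recovered synergy vectors.
#'
#' @param W Planted synergy matrix (8 x k, generator units).
#' @param C_params Activation bump parameters.
#' @return 8 x k matrix, columns unit-max.
#' @export
analysis_space_truth <- function(W, C_params) {
  pct <- seq(0, 100, by = 0.1)
  Cw <- activation_bumps(C_params, pct)
  E <- W %*% Cw
  norm_m <- apply(E, 1, max)
  burst_rows <- c("R_BFLH", "S_BFLH")
  norm_m[burst_rows] <- pmax(norm_m[burst_rows],
                             stabilization_burst_amp() + 0.02 * rowSums(W)[burst_rows])
  Wn <- sweep(W, 2, C_params$amplitude, "*") / norm_m
  sweep(Wn, 2, apply(Wn, 2, max), "/")
}

# Minimum-jerk position profile s(u) on u in [0, 1].
minjerk <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  10 * u^3 - 15 * u^4 + 6 * u^5
}

#' Synthesize one trial of marker trajectories
#'
#' Places a standing posture scaled to body height, moves the belt marker
#' along the belt profile from the scripted onset, executes a smooth
#' minimum-jerk backward recovery step of the scripted length between
#' liftoff and touchdown (with a small vertical clearance arc), shifts the
#' whole body backwards to emulate the COM excursion, and adds Gaussian
#' marker noise. The posture is consistent with [default_segment_table()],
#' so segmental COM estimates are testable against the generator's own COM.
#'
#' @param script Trial script: `bon_s`, `liftoff_s`, `td_s`,
#'   `step_length_m`, optionally `trunk_angle_deg`, `arm_flexion_deg`,
#'   `com_shift_m`, `recovery_side`.
#' @param body_height_m Participant height, metres.
#' @param belt A [make_belt_profile()].
#' @param rate_hz Frame rate (default 120).
#' @param duration_s Trial length, seconds.
#' @param noise_sd_m Marker noise sd, metres (default 0.001).
#' @param seed Integer seed.
#' @return List with `markers` (a [marker_trial()]) and `com_true`
#'   (noise-free generator COM trajectory, n_frames x 3).
#' @export
synthesize_markers <- function(script, body_height_m = 1.70,
                               belt = make_belt_profile(),
                               rate_hz = 120, duration_s = 8,
                               noise_sd_m = 0.001, seed = 1L) {
  if (!(script$bon_s < script$liftoff_s && script$liftoff_s < script$td_s)) {
    stop("trial script violates event ordering bon < liftoff < td")
  }
  set.seed(seed)
  h <- body_height_m
  n <- round(duration_s * rate_hz)
  tt <- (seq_len(n) - 1) / rate_hz
  rec <- script$recovery_side %||% "right"
  trunk_deg <- script$trunk_angle_deg %||% 87
  arm_deg <- script$arm_flexion_deg %||% 20
  com_shift <- script$com_shift_m %||% 0.05

  hip_z <- 0.53 * h; trunk_len <- 0.29 * h
  arm_len <- 0.186 * h; forearm_len <- 0.254 * h
  sh_ap <- trunk_len * cos(trunk_deg * pi / 180)
  sh_z <- hip_z + trunk_len * sin(trunk_deg * pi / 180)
  el <- c(sh_ap + arm_len * sin(arm_deg * pi / 180), 0,
          sh_z - arm_len * cos(arm_deg * pi / 180))
  base <- list(
    HEAD = c(sh_ap, 0, sh_z + 0.11 * h),
    L_SHOULDER = c(sh_ap, 0.18, sh_z), R_SHOULDER = c(sh_ap, -0.18, sh_z),
    L_ELBOW = c(el[1], 0.20, el[3]), R_ELBOW = c(el[1], -0.20, el[3]),
    L_WRIST = c(el[1] + 0.05, 0.21, el[3] - forearm_len + 0.02),
    R_WRIST = c(el[1] + 0.05, -0.21, el[3] - forearm_len + 0.02),
    L_HIP = c(0, 0.09, hip_z), R_HIP = c(0, -0.09, hip_z),
    L_KNEE = c(0.02, 0.10, 0.285 * h), R_KNEE = c(0.02, -0.10, 0.285 * h),
    L_HEEL = c(0, 0.10, 0.02), R_HEEL = c(0, -0.10, 0.02),
    L_TOE = c(0.15 * h, 0.10, 0.02), R_TOE = c(0.15 * h, -0.10, 0.02),
    BELT = c(0.3, -0.4, 0))
  names_all <- names(base)
  pos <- array(rep(unlist(base), each = n), c(n, 3, length(base)),
               dimnames = list(NULL, c("X", "Y", "Z"), names_all))
  pos <- aperm(pos, c(3, 1, 2))

  # belt translation from scripted onset
  bidx <- findInterval(tt - script$bon_s, belt$time)
  belt_disp <- ifelse(tt < script$bon_s, 0,
                      ifelse(bidx >= length(belt$time), belt$displacement_m,
                             belt$position[pmax(bidx, 1)]))
  pos["BELT", , 1] <- pos["BELT", , 1] + belt_disp

  # whole-body backward COM excursion from onset to just past touchdown
  u_body <- (tt - script$bon_s) / (script$td_s + 0.2 - script$bon_s)
  body_shift <- -com_shift * minjerk(u_body)
  # feet stay planted (or follow their own step script); only the belt moves
  # with the treadmill and the upper body carries the COM excursion
  body_markers <- setdiff(names_all,
                          c("BELT", "L_HEEL", "R_HEEL", "L_TOE", "R_TOE"))
  pos[body_markers, , 1] <- sweep(pos[body_markers, , 1], 2, body_shift, "+")

  # recovery foot: minimum-jerk backward step with vertical clearance
  u <- (tt - script$liftoff_s) / (script$td_s - script$liftoff_s)
  s <- minjerk(u)
  foot <- paste0(if (rec == "right") "R" else "L", c("_HEEL", "_TOE"))
  for (mk in foot) {
    pos[mk, , 1] <- pos[mk, , 1] - script$step_length_m * s
    pos[mk, , 3] <- pos[mk, , 3] + 0.06 * sin(pi * s)
  }

  com_true <- matrix(0, n, 3)
  tab <- default_segment_table()
  for (i in seq_len(nrow(tab))) {
    P <- pos[tab$proximal[i], , ]; D <- pos[tab$distal[i], , ]
    com_true <- com_true + tab$mass_fraction[i] * (P + tab$com_fraction[i] * (D - P))
  }

  if (noise_sd_m > 0) {
    pos <- pos + array(stats::rnorm(length(pos), 0, noise_sd_m), dim(pos))
  }
  list(markers = marker_trial(pos, names_all, rate_hz), com_true = com_true)
}

#' Synthesize a load-cell trace
#'
#' A smooth harness-load pulse around the step, peaking at `peak_bw_frac`
#' of body weight (default 0.10, well under the 30% fall threshold — no
#' participant fell in the study protocol this emulates).
#'
#' @param script Trial script (`bon_s`, `td_s`).
#' @param body_weight_n Body weight, newtons.
#' @param peak_bw_frac Peak force as a fraction of body weight.
#' @param rate_hz Sampling rate.
#' @param duration_s Trial length, seconds.
#' @param seed Integer seed.
#' @return A [loadcell_trial()].
#' @export
synthesize_loadcell <- function(script, body_weight_n, peak_bw_frac = 0.10,
                                rate_hz = 600, duration_s = 8, seed = 1L) {
  set.seed(seed)
  n <- round(duration_s * rate_hz)
  tt <- (seq_len(n) - 1) / rate_hz
  mid <- (script$bon_s + script$td_s) / 2
  pulse <- peak_bw_frac * body_weight_n * exp(-(tt - mid)^2 / (2 * 0.15^2))
  noise <- abs(stats::rnorm(n, 0, 0.002 * body_weight_n))
  loadcell_trial(pulse + noise, rate_hz, body_weight_n)
}

# Defaults for the scripted kinematics, set to the early-stage group means
# and spreads reported for young adults in this protocol, with the
# late-stage shifts of the adaptation (earlier step initiation, longer
# step). All times in seconds, lengths in metres.
kinematic_script_defaults <- function() {
  list(initiation_mean = 0.25, initiation_participant_sd = 0.06,
       initiation_trial_sd = 0.015,
       execution_mean = 0.18, execution_trial_sd = 0.01,
       step_length_mean = 0.17, step_length_participant_sd = 0.04,
       step_length_trial_sd = 0.015,
       late_initiation_shift = -0.03, late_step_length_shift = 0.03,
       trunk_angle_mean = 87, trunk_angle_sd = 2,
       arm_flexion_mean = 20, arm_flexion_sd = 5)
}

#' Generate a complete synthetic training session
#'
#' One participant's 10-trial stance-slip block with known ground truth:
#' per-trial scripted events (belt onset uniform in 2-4 s, step initiation
#' and execution, step length), planted per-participant synergy vectors
#' (template plus weight jitter, sd 0.05), Gaussian-bump activations, and
#' the optional late-stage reweighting and kinematic shifts.
#'
#' @param participant_id Participant identifier.
#' @param gt A [make_ground_truth()].
#' @param reweight Optional reweighting spec: list with `mode` (synergy
#'   index), `muscle` (channel label), `delta` (mean additive weight
#'   change in the late stage) and `sd` (its between-participant sd).
#' @param kin_shift Late-stage kinematic shifts: list with `initiation_s`
#'   and `step_length_m` added to the late-trial scripts (defaults: the
#'   adaptation directions, -0.03 s and +0.03 m).
#' @param n_trials Number of trials (default 10).
#' @param body_height_m,body_weight_kg Anthropometry.
#' @param weight_jitter_sd Sd of the per-participant synergy weight jitter.
#' @param signals Also synthesize EMG/marker/load-cell signals (set FALSE
#'   for fast script-level simulation).
#' @param seed Integer seed.
#' @return A [session()] with a `ground_truth` attribute holding the
#'   participant's true `W_early`, `W_late`, activation parameters and
#'   per-trial scripts; when `signals = FALSE`, only the ground truth list.
#' @export
make_synthetic_session <- function(participant_id, gt = make_ground_truth(),
                                   reweight = NULL, kin_shift = NULL,
                                   n_trials = 10, body_height_m = 1.70,
                                   body_weight_kg = 70,
                                   weight_jitter_sd = 0.05,
                                   signals = TRUE, seed = 1L) {
  set.seed(seed)
  k <- ncol(gt$W_true)
  kd <- kinematic_script_defaults()
  if (is.null(kin_shift)) {
    kin_shift <- list(initiation_s = kd$late_initiation_shift,
                      step_length_m = kd$late_step_length_shift)
  }
  unit_max <- function(W) sweep(W, 2, apply(W, 2, max), "/")
  jitter_W <- function(W) {
    unit_max(pmax(W + matrix(stats::rnorm(length(W), 0, weight_jitter_sd),
                             nrow(W)), 0.01))
  }
  W_early <- jitter_W(gt$W_true)
  W_late_base <- gt$W_true
  if (!is.null(reweight)) {
    mi <- match(reweight$muscle, canonical_channels())
    if (is.na(mi)) stop("unknown muscle in reweighting spec: ", reweight$muscle)
    delta_i <- stats::rnorm(1, reweight$delta, reweight$sd %||% 0)
    W_late_base[mi, reweight$mode] <- max(W_late_base[mi, reweight$mode] + delta_i, 0.01)
  }
  W_late <- jitter_W(W_late_base)
  dimnames(W_late) <- dimnames(W_early) <- dimnames(gt$W_true)

  stages <- default_stage_map(n_trials)
  init_base <- stats::rnorm(1, kd$initiation_mean, kd$initiation_participant_sd)
  sl_base <- stats::rnorm(1, kd$step_length_mean, kd$step_length_participant_sd)
  scripts <- lapply(seq_len(n_trials), function(i) {
    late <- stages[i] == "late"
    initiation <- max(init_base + (if (late) kin_shift$initiation_s else 0) +
                        stats::rnorm(1, 0, kd$initiation_trial_sd), 0.12)
    execution <- max(stats::rnorm(1, kd$execution_mean, kd$execution_trial_sd), 0.12)
    step_len <- max(sl_base + (if (late) kin_shift$step_length_m else 0) +
                      stats::rnorm(1, 0, kd$step_length_trial_sd), 0.08)
    bon <- stats::runif(1, 2, 4)
    list(id = sprintf("S%02d", i), stage = stages[i], bon_s = bon,
         liftoff_s = bon + initiation, td_s = bon + initiation + execution,
         step_initiation_s = initiation, step_execution_s = execution,
         step_length_m = step_len,
         trunk_angle_deg = stats::rnorm(1, kd$trunk_angle_mean, kd$trunk_angle_sd),
         arm_flexion_deg = max(stats::rnorm(1, kd$arm_flexion_mean, kd$arm_flexion_sd), 2),
         recovery_side = "right")
  })
  truth <- list(participant_id = participant_id, W_early = W_early,
                W_late = W_late, C_params = gt$C_params,
                noise_sd = gt$noise_sd, scripts = scripts, seed = seed)
  if (!signals) return(truth)

  belt <- make_belt_profile()
  trial_seeds <- sample.int(.Machine$integer.max - 1L, 3 * n_trials)
  bw_n <- body_weight_kg * 9.81
  trials <- vector("list", n_trials)
  com_true <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    sc <- scripts[[i]]
    Wp <- if (sc$stage == "late") W_late else W_early
    mk <- synthesize_markers(sc, body_height_m, belt,
                             seed = trial_seeds[3 * i - 1])
    trials[[i]] <- list(
      id = sc$id,
      emg = synthesize_emg(Wp, gt$C_params, sc, noise_sd = gt$noise_sd,
                           seed = trial_seeds[3 * i - 2]),
      markers = mk$markers,
      loadcell = synthesize_loadcell(sc, bw_n, seed = trial_seeds[3 * i]),
      recovery_side = sc$recovery_side)
    com_true[[i]] <- mk$com_true
  }
  s <- session(participant_id, trials, body_height_m, body_weight_kg)
  truth$com_true <- com_true
  attr(s, "ground_truth") <- truth
  s
}

#' Generate a synthetic participant cohort
#'
#' Builds `n` seeded sessions sharing one ground truth template. Sub-seeds
#' derive deterministically from `seed`, so the whole cohort is
#' reproducible from a single integer.
#'
#' @param n Cohort size (default 26, the study cohort).
#' @param gt A [make_ground_truth()].
#' @param reweight,kin_shift Passed to [make_synthetic_session()]. By
#'   default no reweighting and the default late-stage kinematic shifts;
#'   pass `kin_shift = list(initiation_s = 0, step_length_m = 0)` for a
#'   null cohort.
#' @param signals Synthesize raw signals (FALSE returns ground truths only).
#' @param seed Integer root seed.
#' @return List of sessions (or ground-truth lists), with attribute
#'   `ground_truth` (the shared template).
#' @export
make_cohort <- function(n = 26, gt = make_ground_truth(), reweight = NULL,
                        kin_shift = NULL, signals = TRUE, seed = 1L) {
  if (n < 3) stop("cohort needs at least 3 participants")
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  out <- lapply(seq_len(n), function(i) {
    make_synthetic_session(sprintf("P%02d", i), gt, reweight = reweight,
                           kin_shift = kin_shift, signals = signals,
                           seed = seeds[i])
  })
  names(out) <- sprintf("P%02d", seq_len(n))
  attr(out, "ground_truth") <- gt
  out
}
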