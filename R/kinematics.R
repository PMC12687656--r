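#' Low-pass filter marker trajectories
#'
#' Zero-phase dual-pass Butterworth (order 2 per pass, effective 4th order)
#' applied to every coordinate of every marker. Coordinates containing
#' missing frames are left unfiltered.
#'
#' @param m A [marker_trial()].
#' @param cutoff_hz Cutoff frequency, Hz (default 6).
#' @return Filtered [marker_trial()].
#' @export
lowpass_markers <- function(m, cutoff_hz = 6) {
  nyq <- m$rate_hz / 2
  if (cutoff_hz >= nyq) stop("cutoff at or above Nyquist frequency")
  bf <- signal::butter(2, cutoff_hz / nyq, type = "low")
  pos <- m$positions
  for (i in seq_len(dim(pos)[1])) {
    for (j in 1:3) {
      v <- pos[i, , j]
      if (!anyNA(v)) pos[i, , j] <- filtfilt_pad(bf, v)
    }
  }
  out <- marker_trial(pos, m$marker_names, m$rate_hz)
  attr(out, "gap_report") <- attr(m, "gap_report")
  out
}

# Central-difference velocity (one-sided at the ends), same length as x.
central_velocity <- function(x, rate_hz) {
  n <- length(x)
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate_hz / 2
  v[1] <- (x[2] - x[1]) * rate_hz
  v[n] <- (x[n] - x[n - 1]) * rate_hz
  v
}

# Rising-edge crossing time of the super-threshold run containing the peak
# at `peak`: walk backward to the last sub-threshold frame and interpolate
# the crossing linearly between frames. Requires the run to hold threshold
# for at least `sustain` frames, rejecting isolated noise spikes.
run_onset_time <- function(v, peak, thresh, rate_hz, sustain = 3L) {
  i0 <- peak
  while (i0 > 1 && v[i0 - 1] > thresh) i0 <- i0 - 1L
  run_len <- 0L
  while (i0 + run_len <= length(v) && v[i0 + run_len] > thresh) run_len <- run_len + 1L
  if (run_len < sustain) return(NA_real_)
  if (i0 == 1) return(0)
  frac <- (thresh - v[i0 - 1]) / (v[i0] - v[i0 - 1])
  (i0 - 2 + frac) / rate_hz
}

# Falling-edge crossing after `peak`: first frame below threshold that stays
# below for `sustain` frames, with linear sub-frame interpolation.
run_offset_time <- function(v, peak, thresh, rate_hz, sustain = 3L) {
  n <- length(v)
  i <- peak
  repeat {
    while (i < n && v[i] > thresh) i <- i + 1L
    if (v[i] > thresh) return(NA_real_)       # ran off the end
    below <- 0L
    while (i + below <= n && v[i + below] < thresh) below <- below + 1L
    if (below >= sustain || i + below > n) break
    i <- i + below
  }
  frac <- (v[i - 1] - thresh) / (v[i - 1] - v[i])
  (i - 2 + frac) / rate_hz
}

#' Detect belt onset (BON)
#'
#' Belt onset is the instant the belt marker's anteroposterior velocity
#' first exceeds `v_thresh` (0.05 m/s) on its way to the belt-pulse peak:
#' the detector anchors on the velocity peak, walks back to the threshold
#' crossing of the contiguous super-threshold run (which must hold for at
#' least `sustain` frames), and interpolates the crossing time between
#' frames. Anchoring on the peak makes the rule robust to threshold-grazing
#' noise excursions far from the perturbation.
#'
#' @param m A (filtered) [marker_trial()] containing a `BELT` marker.
#' @param v_thresh Velocity threshold, m/s.
#' @param sustain Minimum consecutive frames above threshold.
#' @return Time of belt onset, seconds.
#' @export
detect_bon <- function(m, v_thresh = 0.05, sustain = 3L) {
  ap <- marker_xyz(m, "BELT")[, 1]
  v <- central_velocity(ap, m$rate_hz)
  peak <- which.max(v)
  if (v[peak] <= v_thresh) stop("belt never exceeds the onset velocity threshold")
  t <- run_onset_time(v, peak, v_thresh, m$rate_hz, sustain)
  if (is.na(t)) stop("belt never exceeds the onset velocity threshold")
  t
}

#' Detect recovery-foot liftoff and touchdown from the heel marker
#'
#' The step is located by the peak of the heel's absolute AP velocity after
#' belt onset. Liftoff is the rising-edge crossing of `v_thresh` of the
#' contiguous super-threshold run containing that peak and touchdown (TD)
#' the falling-edge crossing after it (each sustained for at least
#' `sustain` frames, crossings interpolated between frames).
#'
#' @param m A (filtered) [marker_trial()].
#' @param heel Heel marker name (e.g. `"R_HEEL"`).
#' @param bon_s Belt onset time, seconds.
#' @param v_thresh Velocity threshold, m/s.
#' @param sustain Minimum consecutive frames.
#' @return List with `liftoff_s`, `td_s`.
#' @export
detect_step_events <- function(m, heel, bon_s, v_thresh = 0.05, sustain = 3L) {
  ap <- marker_xyz(m, heel)[, 1]
  v <- abs(central_velocity(ap, m$rate_hz))
  i_bon <- floor(bon_s * m$rate_hz) + 2L
  if (i_bon >= length(v)) stop("belt onset at the end of the trial")
  seg <- v[i_bon:length(v)]
  peak <- i_bon + which.max(seg) - 1L
  if (v[peak] <= v_thresh) stop("no heel liftoff detected after belt onset")
  lo <- run_onset_time(v, peak, v_thresh, m$rate_hz, sustain)
  if (is.na(lo)) stop("no heel liftoff detected after belt onset")
  td <- run_offset_time(v, peak, v_thresh, m$rate_hz, sustain)
  if (is.na(td)) stop("no heel touchdown detected after liftoff")
  list(liftoff_s = lo, td_s = td)
}

#' Detect all trial events
#'
#' Runs [detect_bon()] then [detect_step_events()] on the recovery heel and
#' enforces the ordering `bon < liftoff < td`.
#'
#' @param m A (filtered) [marker_trial()].
#' @param recovery_side `"left"` or `"right"`.
#' @param v_thresh Velocity threshold, m/s.
#' @return List of class `trial_events`: `bon_s`, `liftoff_s`, `td_s`,
#'   `recovery_side`.
#' @export
detect_events <- function(m, recovery_side = "right", v_thresh = 0.05) {
  recovery_side <- match.arg(recovery_side, c("left", "right"))
  heel <- if (recovery_side == "right") "R_HEEL" else "L_HEEL"
  bon_s <- detect_bon(m, v_thresh)
  st <- detect_step_events(m, heel, bon_s, v_thresh)
  ev <- list(bon_s = bon_s, liftoff_s = st$liftoff_s, td_s = st$td_s,
             recovery_side = recovery_side)
  if (!(ev$bon_s < ev$liftoff_s && ev$liftoff_s < ev$td_s)) {
    stop(sprintf("event ordering violated: BON %.3f, liftoff %.3f, TD %.3f",
                 ev$bon_s, ev$liftoff_s, ev$td_s))
  }
  class(ev) <- "trial_events"
  ev
}

#' Step timing and geometry
#'
#' Step initiation time runs from belt onset to recovery-foot liftoff and
#' execution time from liftoff to touchdown. Step length is the AP distance
#' from the recovery heel to the slipping heel at touchdown (positive for a
#' backward recovery step); step width is the absolute ML distance between
#' the heels at touchdown.
#'
#' @param m A (filtered) [marker_trial()].
#' @param events A `trial_events`.
#' @return List with `step_initiation_s`, `step_execution_s`,
#'   `step_length_m`, `step_width_m`.
#' @export
step_metrics <- function(m, events) {
  rec <- if (events$recovery_side == "right") "R_HEEL" else "L_HEEL"
  slp <- if (events$recovery_side == "right") "L_HEEL" else "R_HEEL"
  i_td <- floor(events$td_s * m$rate_hz) + 1L
  rh <- marker_xyz(m, rec)[i_td, ]
  sh <- marker_xyz(m, slp)[i_td, ]
  list(step_initiation_s = events$liftoff_s - events$bon_s,
       step_execution_s = events$td_s - events$liftoff_s,
       step_length_m = sh[1] - rh[1],
       step_width_m = abs(sh[2] - rh[2]))
}

#' Default segmental anthropometric table
#'
#' Thirteen segments (bilateral thigh, shank, foot, upper arm,
#' forearm+hand, hemitrunk, plus the head as a point mass) defined by
#' proximal/distal marker pairs, with mass fractions summing to 1 and the
#' segment centre of mass placed a fraction of the way from the proximal to
#' the distal marker. Values follow standard segmental anthropometry,
#' halved across sides for the paired segments. Fully overridable: any
#' table with the same columns works, and the synthetic-data generator uses
#' this same table so COM recovery is testable end-to-end.
#'
#' @return Data frame: `segment`, `proximal`, `distal`, `mass_fraction`,
#'   `com_fraction`.
#' @export
default_segment_table <- function() {
  tab <- rbind(
    data.frame(segment = c("thigh", "shank", "foot", "upper_arm", "forearm_hand", "hemitrunk"),
               proximal = c("HIP", "KNEE", "HEEL", "SHOULDER", "ELBOW", "HIP"),
               distal = c("KNEE", "HEEL", "TOE", "ELBOW", "WRIST", "SHOULDER"),
               mass_fraction = c(0.100, 0.0465, 0.0145, 0.028, 0.022, 0.2485),
               com_fraction = c(0.433, 0.433, 0.500, 0.436, 0.580, 0.500)))
  both <- do.call(rbind, lapply(c("L", "R"), function(s) {
    d <- tab
    d$segment <- paste(s, d$segment, sep = "_")
    d$proximal <- paste(s, d$proximal, sep = "_")
    d$distal <- paste(s, d$distal, sep = "_")
    d
  }))
  rbind(both,
        data.frame(segment = "head", proximal = "HEAD", distal = "HEAD",
                   mass_fraction = 0.081, com_fraction = 0))
}

#' Whole-body centre of mass from a segmental model
#'
#' COM per frame as the mass-fraction-weighted sum of segment centres, each
#' segment centre lying `com_fraction` of the way from its proximal to its
#' distal marker.
#'
#' @param m A [marker_trial()].
#' @param table Segment parameter table (see [default_segment_table()]);
#'   mass fractions must sum to 1 within 1e-6.
#' @return Numeric matrix `[n_frames x 3]` (X = AP, Y = ML, Z = vertical).
#' @export
com_estimate <- function(m, table = default_segment_table()) {
  if (abs(sum(table$mass_fraction) - 1) > 1e-6) {
    stop("segment mass fractions must sum to 1")
  }
  need <- unique(c(table$proximal, table$distal))
  missing <- setdiff(need, m$marker_names)
  if (length(missing)) stop("segment table references missing marker(s): ",
                            paste(missing, collapse = ", "))
  com <- matrix(0, dim(m$positions)[2], 3)
  for (i in seq_len(nrow(table))) {
    P <- marker_xyz(m, table$proximal[i])
    D <- marker_xyz(m, table$distal[i])
    com <- com + table$mass_fraction[i] * (P + table$com_fraction[i] * (D - P))
  }
  colnames(com) <- c("X", "Y", "Z")
  com
}

#' COM position and velocity relative to the base of support at touchdown
#'
#' AP COM position is the AP distance from the recovery heel to the
#' projected COM at touchdown, normalized by base-of-support length (the AP
#' distance from the trailing heel to the leading toe, resolved by AP
#' ordering at that frame). ML COM position is the smaller ML distance from
#' the COM to either BOS edge (the two toe markers), normalized by BOS
#' width. AP COM velocity is the COM velocity minus the recovery-heel
#' velocity; ML COM velocity is the absolute ML velocity (the BOS does not
#' move mediolaterally). Velocities are central differences on the filtered
#' trajectories.
#'
#' @param com COM trajectory from [com_estimate()].
#' @param m The (filtered) [marker_trial()].
#' @param events A `trial_events`.
#' @return List with `ap_com_pos_norm`, `ml_com_pos_norm`, `ap_com_vel_mps`,
#'   `ml_com_vel_mps`.
#' @export
com_state <- function(com, m, events) {
  i_td <- floor(events$td_s * m$rate_hz) + 1L
  rec <- if (events$recovery_side == "right") "R_HEEL" else "L_HEEL"
  heels <- c(marker_xyz(m, "L_HEEL")[i_td, 1], marker_xyz(m, "R_HEEL")[i_td, 1])
  toes <- c(marker_xyz(m, "L_TOE")[i_td, 1], marker_xyz(m, "R_TOE")[i_td, 1])
  bos_len <- max(toes) - min(heels)
  if (bos_len <= 0) stop("degenerate base of support (length <= 0)")
  toes_ml <- c(marker_xyz(m, "L_TOE")[i_td, 2], marker_xyz(m, "R_TOE")[i_td, 2])
  bos_wid <- abs(diff(toes_ml))
  if (bos_wid <= 0) stop("degenerate base of support (width <= 0)")
  rh_ap <- marker_xyz(m, rec)[, 1]
  v_com_ap <- central_velocity(com[, 1], m$rate_hz)[i_td]
  v_com_ml <- central_velocity(com[, 2], m$rate_hz)[i_td]
  v_rh <- central_velocity(rh_ap, m$rate_hz)[i_td]
  list(
    ap_com_pos_norm = (com[i_td, 1] - rh_ap[i_td]) / bos_len,
    ml_com_pos_norm = min(abs(com[i_td, 2] - toes_ml)) / bos_wid,
    ap_com_vel_mps = v_com_ap - v_rh,
    ml_com_vel_mps = abs(v_com_ml))
}

#' Trunk and arm angles at touchdown
#'
#' Trunk angle is the elevation of the hip-midpoint to shoulder-midpoint
#' vector above the transverse (horizontal) plane in the sagittal
#' direction: 90 degrees when upright, below 90 for trunk flexion
#' (forward lean), above 90 for extension. Arm angle is the angle between
#' the shoulder-to-elbow vector and the downward vertical in the sagittal
#' plane, per arm; the arm
#' with the larger flexion angle is reported.
#'
#' @param m A (filtered) [marker_trial()].
#' @param events A `trial_events`.
#' @return List with `trunk_angle_deg`, `arm_flexion_deg`.
#' @export
trunk_arm_angles <- function(m, events) {
  i_td <- floor(events$td_s * m$rate_hz) + 1L
  sh <- (marker_xyz(m, "L_SHOULDER")[i_td, ] + marker_xyz(m, "R_SHOULDER")[i_td, ]) / 2
  hp <- (marker_xyz(m, "L_HIP")[i_td, ] + marker_xyz(m, "R_HIP")[i_td, ]) / 2
  v <- sh - hp
  if (sqrt(sum(v^2)) < 1e-9) stop("coincident shoulder and hip midpoints")
  trunk <- atan2(v[3], v[1]) * 180 / pi
  arm <- vapply(c("L", "R"), function(s) {
    if (!all(paste0(s, c("_SHOULDER", "_ELBOW")) %in% m$marker_names)) return(NA_real_)
    a <- marker_xyz(m, paste0(s, "_ELBOW"))[i_td, ] -
         marker_xyz(m, paste0(s, "_SHOULDER"))[i_td, ]
    len <- sqrt(a[1]^2 + a[3]^2)          # sagittal-plane projection
    if (len < 1e-9) stop("coincident shoulder and elbow markers")
    acos(pmin(pmax(-a[3] / len, -1), 1)) * 180 / pi
  }, 1)
  list(trunk_angle_deg = unname(trunk),
       arm_flexion_deg = max(arm, na.rm = TRUE))
}

#' Fall classification from the harness load cell
#'
#' A trial counts as a fall when the peak harness force strictly exceeds
#' `thresh_pct`% of body weight.
#'
#' @param lc A [loadcell_trial()].
#' @param thresh_pct Threshold, percent of body weight (default 30).
#' @return Logical.
#' @export
detect_fall <- function(lc, thresh_pct = 30) {
  if (lc$body_weight_n <= 0) stop("body weight must be positive")
  max(lc$force) > thresh_pct / 100 * lc$body_weight_n
}

#' All kinematic outcomes for one trial
#'
#' Filters the markers, detects the events, and computes step metrics, COM
#' state, trunk/arm angles and the fall classification.
#'
#' @param markers A raw [marker_trial()].
#' @param loadcell A [loadcell_trial()].
#' @param recovery_side `"left"` or `"right"`.
#' @param cfg A [pipeline_config()].
#' @param segment_table Segmental model table for [com_estimate()].
#' @return One-row data frame of outcomes plus the detected event times.
#' @export
trial_kinematics <- function(markers, loadcell, recovery_side = "right",
                             cfg = pipeline_config(),
                             segment_table = default_segment_table()) {
  mf <- lowpass_markers(markers, cfg$marker_lp_hz)
  mev <- lowpass_markers(markers, cfg$event_lp_hz)
  ev <- detect_events(mev, recovery_side, cfg$belt_v_thresh)
  sm <- step_metrics(mf, ev)
  com <- com_estimate(mf, segment_table)
  cs <- com_state(com, mf, ev)
  ta <- trunk_arm_angles(mf, ev)
  data.frame(bon_s = ev$bon_s, liftoff_s = ev$liftoff_s, td_s = ev$td_s,
             as.data.frame(sm), as.data.frame(cs), as.data.frame(ta),
             fall = detect_fall(loadcell, cfg$fall_thresh_pct))
}
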