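#' Per-trial time-normalized activation curves of a synergy fit
#'
#' Splits each activation coefficient row at the trial boundaries of the
#' concatenated stage matrix, time-normalizes each trial's segment to
#' `n_out` points and averages across trials.
#'
#' @param fit A `synergy_fit` whose matrix came from
#'   [concatenate_envelopes()].
#' @param n_out Points per normalized curve.
#' @return Matrix `n_out x K`, one mean activation curve per synergy.
#' @export
synergy_activation_curves <- function(fit, n_out = 100) {
  bounds <- fit$m$trial_boundaries
  ends <- c(bounds[-1] - 1L, ncol(fit$C))
  vapply(seq_len(fit$K), function(i) {
    segs <- vapply(seq_along(bounds), function(j) {
      time_normalize(fit$C[i, bounds[j]:ends[j]], n_out)
    }, numeric(n_out))
    rowMeans(segs)
  }, numeric(n_out))
}

# Envelope -> window -> bin for every trial of a session, using detected
# events. Returns the windowed per-trial envelope matrices plus the
# whole-trial binned envelopes from which the session normalization maxima
# are taken (the protocol normalizes to the maximum activation anywhere in
# the trials, not only inside the analysis window).
session_envelopes <- function(s, events, cfg) {
  windowed <- vector("list", length(s$trials))
  full <- vector("list", length(s$trials))
  for (i in seq_along(s$trials)) {
    env <- emg_envelope(s$trials[[i]]$emg, cfg$emg_hp_hz, cfg$emg_lp_hz)
    full[[i]] <- bin_average(env, cfg$bin_ms)
    windowed[[i]] <- bin_average(
      window_trial(env, events[[i]], cfg$pre_ms, cfg$post_ms), cfg$bin_ms)
  }
  list(windowed = windowed, full = full)
}

#' Extract early- and late-stage synergies for one session
#'
#' Preprocesses every trial (envelope, window on the detected events, bin),
#' computes the session-wide per-muscle normalization maxima over all
#' trials, builds the concatenated early and late stage matrices, selects
#' the synergy dimensionality per stage and returns unit-max synergy sets
#' restored to their original scaling.
#'
#' @param s A [session()].
#' @param events List of per-trial event lists (`bon_s`, `td_s`), e.g. from
#'   [detect_events()] on each trial.
#' @param cfg A [pipeline_config()].
#' @param seed Integer seed.
#' @return List with `early`, `late` (unit-max `synergy_fit`s) and
#'   `norm_factors`.
#' @export
extract_session_synergies <- function(s, events, cfg = pipeline_config(),
                                      seed = cfg$seed) {
  envs <- session_envelopes(s, events, cfg)
  mats <- envs$windowed
  nf <- max_norm_factors(envs$full)
  set.seed(seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 2)
  fit_stage <- function(stage, sseed) {
    idx <- which(s$stage_map == stage)
    if (!length(idx)) stop("no trials in stage ", stage)
    m <- scale_unit_variance(normalize_max(concatenate_envelopes(mats[idx]), nf))
    unscale_and_normalize(select_dimensionality(m, cfg = cfg, seed = sseed))
  }
  list(early = fit_stage("early", stage_seeds[1]),
       late = fit_stage("late", stage_seeds[2]),
       norm_factors = nf)
}

#' Run the full two-stage analysis on a cohort of sessions
#'
#' Executes the complete pipeline: per-trial kinematics and event
#' detection, per-participant preprocessing and synergy extraction with
#' dimensionality selection for the early and late stages, cross-participant
#' pooling and silhouette-guided mode clustering per stage, mode naming and
#' cross-stage matching, per-mode paired comparisons of muscle weights and
#' activation features, and the cohort-level kinematic statistics
#' (repeated-measures ANOVA across trials S1, S2, S9, S10 and paired
#' early/late t-tests; Wilcoxon signed-rank on synergy dimensionality).
#'
#' @param sessions List of [session()] objects (one per participant).
#' @param cfg A [pipeline_config()].
#' @return Object of class `stage_report` with elements `kinematics`,
#'   `kin_stats`, `dimensionality`, `dim_test`, `fits`, `modes`
#'   (`early`/`late` `clustered_modes`), `match`, `weight_stats`,
#'   `feature_stats`, `features`, `config`.
#' @export
analyze_cohort <- function(sessions, cfg = pipeline_config()) {
  ids <- vapply(sessions, function(s) s$participant_id, "")
  names(sessions) <- ids
  set.seed(cfg$seed)
  part_seeds <- sample.int(.Machine$integer.max - 1L, length(sessions) + 2L)

  # --- kinematics and events ------------------------------------------------
  kin_rows <- list(); events_all <- list()
  for (p in seq_along(sessions)) {
    s <- sessions[[p]]
    ev_list <- vector("list", length(s$trials))
    for (i in seq_along(s$trials)) {
      tr <- s$trials[[i]]
      mf <- lowpass_markers(tr$markers, cfg$marker_lp_hz)
      mev <- lowpass_markers(tr$markers, cfg$event_lp_hz)
      ev <- detect_events(mev, tr$recovery_side %||% "right", cfg$belt_v_thresh)
      sm <- step_metrics(mf, ev)
      com <- com_estimate(mf)
      cs <- com_state(com, mf, ev)
      ta <- trunk_arm_angles(mf, ev)
      ev_list[[i]] <- ev
      kin_rows[[length(kin_rows) + 1L]] <- data.frame(
        participant = s$participant_id, trial = i, stage = s$stage_map[i],
        bon_s = ev$bon_s, liftoff_s = ev$liftoff_s, td_s = ev$td_s,
        as.data.frame(sm), as.data.frame(cs), as.data.frame(ta),
        fall = detect_fall(tr$loadcell, cfg$fall_thresh_pct),
        stringsAsFactors = FALSE)
    }
    events_all[[s$participant_id]] <- ev_list
  }
  kinematics <- do.call(rbind, kin_rows)

  # --- per-participant synergy extraction -----------------------------------
  fits <- list(early = list(), late = list())
  curves <- list(early = list(), late = list())
  for (p in seq_along(sessions)) {
    s <- sessions[[p]]
    sy <- extract_session_synergies(s, events_all[[s$participant_id]], cfg,
                                    seed = part_seeds[p])
    for (st in c("early", "late")) {
      fits[[st]][[s$participant_id]] <- sy[[st]]
      curves[[st]][[s$participant_id]] <- synergy_activation_curves(sy[[st]])
    }
  }
  dimensionality <- data.frame(
    participant = ids,
    early = vapply(fits$early[ids], function(f) as.integer(f$K), 1L),
    late = vapply(fits$late[ids], function(f) as.integer(f$K), 1L))
  dim_test <- wilcoxon_signed_rank(dimensionality$early, dimensionality$late)

  # --- clustering, naming, matching -----------------------------------------
  modes <- list()
  for (st in c("early", "late")) {
    sd_idx <- length(sessions) + if (st == "early") 1L else 2L
    cm <- cluster_stage(fits[[st]], stage = st, cfg = cfg,
                        seed = part_seeds[sd_idx])
    curve_mat <- do.call(cbind, curves[[st]][ids])
    mode_curves <- vapply(seq_len(cm$chosen_k), function(j) {
      rowMeans(curve_mat[, cm$assignments == j, drop = FALSE])
    }, numeric(100))
    modes[[st]] <- name_and_order(cm, mode_curves)
  }
  match <- match_stages(modes$early, modes$late, cfg$similarity_r)

  # --- per-mode paired statistics -------------------------------------------
  weight_stats <- list(); feature_stats <- list(); feature_tabs <- list()
  part_features <- function(cm, st, mode_j) {
    sel <- cm$assignments == mode_j
    who <- cm$provenance$participant[sel]
    syn <- cm$provenance$synergy[sel]
    rows <- lapply(unique(who), function(pp) {
      cv <- rowMeans(curves[[st]][[pp]][, syn[who == pp], drop = FALSE])
      f <- activation_features(cv, cfg$onset_frac_pct)
      data.frame(participant = pp, peak_amp = f$peak_amp, area = f$area,
                 peak_time_pct = f$peak_time_pct, onset_pct = f$onset_pct,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  for (r in seq_len(nrow(match$pairs))) {
    em <- match$pairs$early[r]; lm <- match$pairs$late[r]
    ws <- tryCatch(compare_mode_weights(modes$early, modes$late, em, lm),
                   error = function(e) {
                     warning("weight comparison skipped for mode ", em, ": ",
                             conditionMessage(e)); NULL })
    if (!is.null(ws)) { ws$mode <- em; weight_stats[[r]] <- ws }
    ef <- part_features(modes$early, "early", match(em, modes$early$mode_names))
    lf <- part_features(modes$late, "late", match(lm, modes$late$mode_names))
    feature_tabs[[em]] <- list(early = ef, late = lf)
    fs <- tryCatch(compare_features(ef, lf),
                   error = function(e) {
                     warning("feature comparison skipped for mode ", em, ": ",
                             conditionMessage(e)); NULL })
    if (!is.null(fs)) { fs$mode <- em; feature_stats[[r]] <- fs }
  }

  # --- cohort kinematic statistics ------------------------------------------
  kin_vars <- c("step_initiation_s", "step_execution_s", "step_length_m",
                "step_width_m", "ap_com_pos_norm", "ml_com_pos_norm",
                "ap_com_vel_mps", "ml_com_vel_mps", "trunk_angle_deg",
                "arm_flexion_deg")
  anl <- kinematics[kinematics$stage %in% c("early", "late"), ]
  kin_stats <- do.call(rbind, lapply(kin_vars, function(v) {
    bytrial <- stats::reshape(
      anl[, c("participant", "trial", v)], timevar = "trial",
      idvar = "participant", direction = "wide")
    mat <- as.matrix(bytrial[, -1])
    rm <- tryCatch(rm_anova(mat), error = function(e) NULL)
    agg <- stats::aggregate(anl[[v]], by = list(participant = anl$participant,
                                                stage = anl$stage), mean)
    e <- agg$x[agg$stage == "early"][order(agg$participant[agg$stage == "early"])]
    l <- agg$x[agg$stage == "late"][order(agg$participant[agg$stage == "late"])]
    pt <- paired_t(e, l)
    data.frame(variable = v, mean_early = mean(e), mean_late = mean(l),
               F = if (is.null(rm)) NA_real_ else rm$statistic,
               F_p = if (is.null(rm)) NA_real_ else rm$p,
               t = pt$statistic, t_p = pt$p, d = pt$effect_size_d,
               stringsAsFactors = FALSE)
  }))

  structure(
    list(kinematics = kinematics, kin_stats = kin_stats,
         dimensionality = dimensionality, dim_test = dim_test,
         fits = fits, curves = curves, modes = modes, match = match,
         weight_stats = if (length(weight_stats)) do.call(rbind, weight_stats) else NULL,
         feature_stats = if (length(feature_stats)) do.call(rbind, feature_stats) else NULL,
         features = feature_tabs, config = cfg),
    class = "stage_report")
}

#' @export
print.stage_report <- function(x, ...) {
  cat("== Stance-slip training analysis ==\n")
  cat(sprintf("Participants: %d; falls: %d/%d trials\n",
              nrow(x$dimensionality), sum(x$kinematics$fall), nrow(x$kinematics)))
  cat(sprintf("Synergy dimensionality: early %s, late %s (Wilcoxon p = %.3f)\n",
              paste(range(x$dimensionality$early), collapse = "-"),
              paste(range(x$dimensionality$late), collapse = "-"),
              x$dim_test$p))
  cat(sprintf("Modes: early %d (%s); late %d (%s)\n",
              x$modes$early$chosen_k, paste(x$modes$early$mode_names, collapse = ", "),
              x$modes$late$chosen_k, paste(x$modes$late$mode_names, collapse = ", ")))
  cat("Cross-stage matches:\n")
  print(x$match$pairs, row.names = FALSE)
  cat("Kinematic stage comparison:\n")
  print(x$kin_stats[, c("variable", "mean_early", "mean_late", "t_p", "d")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the pipeline on a directory tree of session files
#'
#' Reads every participant sub-directory (each holding a `session.yaml`
#' manifest plus per-trial CSV files, as written by [write_session()]),
#' runs [analyze_cohort()] and optionally writes the report tables.
#'
#' @param dir Directory containing one sub-directory per participant.
#' @param cfg A [pipeline_config()] (or path to a YAML config).
#' @param out_dir Optional output directory for the report tables.
#' @return A `stage_report`.
#' @export
run_pipeline <- function(dir, cfg = pipeline_config(), out_dir = NULL) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  subs <- list.dirs(dir, recursive = FALSE)
  subs <- subs[file.exists(file.path(subs, "session.yaml"))]
  if (!length(subs)) stop("no session directories found under ", dir)
  sessions <- lapply(subs, read_session)
  report <- analyze_cohort(sessions, cfg)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write the report tables of a `stage_report`
#'
#' Emits the kinematic outcome table, the per-variable statistics, the
#' dimensionality table, per-stage mode reports (centroid weights, member
#' counts, matched r), the paired weight/feature statistics as CSV, and
#' the synergy sets as JSON.
#'
#' @param report A `stage_report`.
#' @param out_dir Output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    if (!is.null(df)) utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  w(report$kinematics, "kinematics.csv")
  w(report$kin_stats, "kinematic_stats.csv")
  w(report$dimensionality, "dimensionality.csv")
  w(report$weight_stats, "weight_stats.csv")
  w(report$feature_stats, "feature_stats.csv")
  for (st in c("early", "late")) {
    cm <- report$modes[[st]]
    r_by_mode <- rep(NA_real_, cm$chosen_k)
    key <- if (st == "early") report$match$pairs$early else report$match$pairs$late
    r_by_mode[match(key, cm$mode_names)] <- report$match$pairs$r
    w(data.frame(mode = cm$mode_names, t(cm$centroids),
                 members = tabulate(cm$assignments, cm$chosen_k),
                 matched_r = r_by_mode, check.names = FALSE),
      sprintf("modes_%s.csv", st))
  }
  syn <- lapply(c("early", "late"), function(st) {
    lapply(report$fits[[st]], function(f) {
      list(K = f$K, W = unname(f$W), C = unname(f$C),
           vaf_global = f$vaf_global, vaf_muscle = unname(f$vaf_muscle),
           seed = f$seed)
    })
  })
  names(syn) <- c("early", "late")
  jsonlite::write_json(syn, file.path(out_dir, "synergies.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
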