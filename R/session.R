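#' Training-session container
#'
#' One participant's block of repeated slip trials. Each trial bundles EMG,
#' marker and load-cell recordings on a common clock. By the default stage
#' map the first two trials form the early-training stage and the last two
#' (trials 9-10 of a 10-trial block) the late-training stage.
#'
#' @param participant_id Participant identifier.
#' @param trials List of trial bundles; each a list with `id`, `emg`
#'   ([emg_trial()]), `markers` ([marker_trial()]), `loadcell`
#'   ([loadcell_trial()]), and optionally `recovery_side` (`"left"`/`"right"`).
#' @param body_height_m,body_weight_kg Anthropometry.
#' @param stage_map Optional character vector of stages per trial; defaults
#'   to early for trials 1-2, late for the last two trials, other elsewhere.
#' @export
session <- function(participant_id, trials, body_height_m, body_weight_kg,
                    stage_map = NULL) {
  n <- length(trials)
  if (n < 1) stop("session needs at least one trial")
  if (is.null(stage_map)) stage_map <- default_stage_map(n)
  if (length(stage_map) != n) stop("stage_map length must match trial count")
  for (i in seq_len(n)) trials[[i]]$stage <- stage_map[i]
  structure(
    list(participant_id = participant_id, trials = trials,
         body_height_m = body_height_m, body_weight_kg = body_weight_kg,
         stage_map = stage_map),
    class = "session")
}

#' @rdname session
#' @param n_trials Number of trials in the block.
#' @export
default_stage_map <- function(n_trials) {
  stages <- rep("other", n_trials)
  stages[seq_len(min(2, n_trials))] <- "early"
  if (n_trials >= 4) stages[(n_trials - 1):n_trials] <- "late"
  stages
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session '%s'> %d trials (stages: %s); height %.2f m, weight %.1f kg\n",
              x$participant_id, length(x$trials),
              paste(x$stage_map, collapse = ","),
              x$body_height_m, x$body_weight_kg))
  invisible(x)
}

#' Trials belonging to one stage
#' @param s A [session()].
#' @param stage `"early"` or `"late"` (or `"other"`).
#' @export
stage_trials <- function(s, stage) {
  s$trials[vapply(s$trials, function(tr) identical(tr$stage, stage), TRUE)]
}

#' Write a session to a directory of CSV files plus a YAML manifest
#'
#' Writes `emg_<id>.csv`, `markers_<id>.csv`, `loadcell_<id>.csv` per trial
#' and a `session.yaml` manifest with participant metadata, trial order and
#' the stage map.
#'
#' @param s A [session()].
#' @param dir Output directory (created if needed).
#' @export
write_session <- function(s, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    participant_id = s$participant_id,
    body_height_m = s$body_height_m,
    body_weight_kg = s$body_weight_kg,
    stage_map = as.list(s$stage_map),
    trials = lapply(s$trials, function(tr) {
      list(id = tr$id,
           emg = sprintf("emg_%s.csv", tr$id),
           markers = sprintf("markers_%s.csv", tr$id),
           loadcell = sprintf("loadcell_%s.csv", tr$id),
           emg_rate_hz = tr$emg$rate_hz,
           marker_rate_hz = tr$markers$rate_hz,
           recovery_side = tr$recovery_side %||% "right")
    }))
  yaml::write_yaml(manifest, file.path(dir, "session.yaml"))
  for (tr in s$trials) {
    write_emg(tr$emg, file.path(dir, sprintf("emg_%s.csv", tr$id)))
    write_markers(tr$markers, file.path(dir, sprintf("markers_%s.csv", tr$id)))
    write_loadcell(tr$loadcell, file.path(dir, sprintf("loadcell_%s.csv", tr$id)))
  }
  invisible(dir)
}

#' Read a session directory written by [write_session()]
#' @param dir Directory containing `session.yaml` and per-trial CSV files.
#' @return A [session()].
#' @export
read_session <- function(dir) {
  mf_path <- file.path(dir, "session.yaml")
  if (!file.exists(mf_path)) stop("no session.yaml manifest in ", dir)
  mf <- yaml::read_yaml(mf_path)
  bw_n <- mf$body_weight_kg * 9.81
  stage_map <- unlist(mf$stage_map)
  trials <- vector("list", length(mf$trials))
  for (i in seq_along(mf$trials)) {
    e <- mf$trials[[i]]
    trials[[i]] <- list(
      id = e$id,
      emg = read_emg(file.path(dir, e$emg),
                     manifest_entry = list(rate_hz = e$emg_rate_hz,
                                           trial_id = e$id,
                                           stage = stage_map[i])),
      markers = read_markers(file.path(dir, e$markers), rate_hz = e$marker_rate_hz),
      loadcell = read_loadcell(file.path(dir, e$loadcell), body_weight_n = bw_n),
      recovery_side = e$recovery_side %||% "right")
  }
  session(mf$participant_id, trials, mf$body_height_m, mf$body_weight_kg,
          stage_map = stage_map)
}
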