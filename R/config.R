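#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with the protocol
#' defaults. Percentage-valued thresholds are stored as percents (e.g. 90,
#' not 0.9); fraction-looking values are rejected to remove a silent
#' hundred-fold error class.
#'
#' @param emg_hp_hz EMG high-pass cutoff before rectification, Hz.
#' @param emg_lp_hz Envelope low-pass cutoff after rectification, Hz.
#' @param marker_lp_hz Marker trajectory low-pass cutoff for kinematic
#'   quantities, Hz.
#' @param event_lp_hz Gentler low-pass cutoff used only for event-detection
#'   velocities, Hz (preserves onset sharpness).
#' @param bin_ms Envelope bin width, milliseconds.
#' @param pre_ms,post_ms Analysis window margins around belt onset and
#'   touchdown, milliseconds.
#' @param vaf_global_pct Global VAF threshold for dimensionality selection, percent.
#' @param vaf_muscle_pct Per-muscle VAF threshold, percent.
#' @param vaf_gain_pct Maximum mean per-muscle VAF gain from one extra
#'   synergy before stopping, percentage points.
#' @param k_max Largest synergy dimensionality considered.
#' @param cluster_range Candidate cluster numbers for mode clustering.
#' @param similarity_r Pearson r above which two mode centroids count as
#'   highly similar across stages.
#' @param belt_v_thresh Belt / heel AP velocity threshold for event
#'   detection, m/s.
#' @param onset_frac_pct Activation onset threshold, percent of peak.
#' @param fall_thresh_pct Fall rule: peak harness load above this percent of
#'   body weight classifies the trial as a fall.
#' @param nnmf_restarts,nnmf_max_iter,nnmf_tol Factorization restart count,
#'   iteration cap and relative-objective convergence tolerance.
#' @param kmeans_n_init Random initializations per k-means run.
#' @param seed Root seed for all stochastic steps.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(emg_hp_hz = 35, emg_lp_hz = 40, marker_lp_hz = 6,
                            event_lp_hz = 12,
                            bin_ms = 10, pre_ms = 100, post_ms = 100,
                            vaf_global_pct = 90, vaf_muscle_pct = 75,
                            vaf_gain_pct = 5, k_max = 8,
                            cluster_range = 1:8, similarity_r = 0.83,
                            belt_v_thresh = 0.05, onset_frac_pct = 25,
                            fall_thresh_pct = 30, nnmf_restarts = 20,
                            nnmf_max_iter = 2000, nnmf_tol = 1e-6,
                            kmeans_n_init = 100, seed = 1L) {
  cfg <- structure(
    list(emg_hp_hz = emg_hp_hz, emg_lp_hz = emg_lp_hz,
         marker_lp_hz = marker_lp_hz, event_lp_hz = event_lp_hz,
         bin_ms = bin_ms, pre_ms = pre_ms,
         post_ms = post_ms, vaf_global_pct = vaf_global_pct,
         vaf_muscle_pct = vaf_muscle_pct, vaf_gain_pct = vaf_gain_pct,
         k_max = k_max, cluster_range = cluster_range,
         similarity_r = similarity_r, belt_v_thresh = belt_v_thresh,
         onset_frac_pct = onset_frac_pct, fall_thresh_pct = fall_thresh_pct,
         nnmf_restarts = nnmf_restarts, nnmf_max_iter = nnmf_max_iter,
         nnmf_tol = nnmf_tol, kmeans_n_init = kmeans_n_init,
         seed = as.integer(seed)),
    class = "pipeline_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  bad <- character()
  pos <- c("emg_hp_hz", "emg_lp_hz", "marker_lp_hz", "event_lp_hz", "bin_ms", "pre_ms",
           "post_ms", "belt_v_thresh", "nnmf_restarts", "nnmf_max_iter",
           "nnmf_tol", "kmeans_n_init")
  for (f in pos) if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0) bad <- c(bad, f)
  if (cfg$bin_ms <= 0) bad <- c(bad, "bin_ms")
  # percent thresholds: reject fraction-scale values outright
  if (!in_range(cfg$vaf_global_pct, 50, 100)) bad <- c(bad, "vaf_global_pct")
  if (!in_range(cfg$vaf_muscle_pct, 10, 100)) bad <- c(bad, "vaf_muscle_pct")
  if (!in_range(cfg$vaf_gain_pct, 1e-9, 50)) bad <- c(bad, "vaf_gain_pct")
  if (!in_range(cfg$onset_frac_pct, 1, 100)) bad <- c(bad, "onset_frac_pct")
  if (!in_range(cfg$fall_thresh_pct, 1, 100)) bad <- c(bad, "fall_thresh_pct")
  if (!in_range(cfg$similarity_r, -1, 1)) bad <- c(bad, "similarity_r")
  if (cfg$k_max < 1 || cfg$k_max > 8) bad <- c(bad, "k_max")
  if (any(cfg$cluster_range < 1) || any(cfg$cluster_range > 8)) {
    bad <- c(bad, "cluster_range")
  }
  bad <- unique(bad)
  if (length(bad)) {
    stop("invalid configuration field(s): ", paste(bad, collapse = ", "))
  }
  cfg
}

in_range <- function(x, lo, hi) is.numeric(x) && length(x) == 1 && x >= lo && x <= hi

#' Load a pipeline configuration from a YAML file
#'
#' Unspecified fields take the protocol defaults of [pipeline_config()].
#' An empty file (or `NULL` path) yields the full default configuration.
#'
#' @param path YAML file, or `NULL` for defaults.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(pipeline_config())
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop("unknown configuration field(s): ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Save a pipeline configuration to YAML
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (f in names(x)) cat(sprintf("  %-16s %s\n", f, paste(x[[f]], collapse = " ")))
  invisible(x)
}
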