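# Zero-phase filtering with odd-symmetric end padding, so startup
# transients fall on the reflected pad and not on the data.
filtfilt_pad <- function(filt, x) {
  n <- length(x)
  p <- min(n - 1L, 3L * max(length(filt$b), length(filt$a)) * 10L)
  pre <- 2 * x[1] - x[(p + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - p)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(p + 1):(p + n)]
}

#' EMG envelope extraction
#'
#' Standard surface-EMG conditioning: zero-phase (dual-pass) second-order
#' Butterworth high-pass, full-wave rectification, then zero-phase dual-pass
#' second-order Butterworth low-pass smoothing. The dual pass doubles the
#' effective order and cancels phase delay, so onset timing is unbiased.
#' Small negative excursions left by the low-pass ringing are clipped to
#' zero (the factorization downstream requires non-negativity); the clipped
#' fraction of total signal mass is recorded in `attr(, "clipped_mass")`.
#'
#' @param trial An [emg_trial()] of raw EMG.
#' @param hp_hz High-pass cutoff, Hz (default 35).
#' @param lp_hz Low-pass cutoff, Hz (default 40).
#' @return An [emg_trial()] holding the non-negative envelope at the input rate.
#' @export
emg_envelope <- function(trial, hp_hz = 35, lp_hz = 40) {
  nyq <- trial$rate_hz / 2
  if (hp_hz >= nyq || lp_hz >= nyq) {
    stop("filter cutoff at or above Nyquist frequency")
  }
  bh <- signal::butter(2, hp_hz / nyq, type = "high")
  bl <- signal::butter(2, lp_hz / nyq, type = "low")
  env <- t(apply(trial$signal, 1, function(x) {
    x <- filtfilt_pad(bh, x)
    filtfilt_pad(bl, abs(x))
  }))
  total <- sum(abs(env))
  clipped <- sum(abs(env[env < 0]))
  env[env < 0] <- 0
  out <- emg_trial(env, trial$rate_hz, trial$trial_id, trial$stage)
  attr(out, "clipped_mass") <- if (total > 0) clipped / total else 0
  out
}

#' Window a trial around the perturbation response
#'
#' Keeps the samples from `pre_ms` before belt onset to `post_ms` after
#' recovery-foot touchdown (start inclusive, end exclusive) — the span the
#' synergy analysis operates on, covering both the proactive and reactive
#' phases of the response.
#'
#' @param trial An [emg_trial()] (typically an envelope).
#' @param events List with `bon_s` and `td_s` on the trial clock (seconds).
#' @param pre_ms,post_ms Window margins, milliseconds.
#' @return Windowed [emg_trial()].
#' @export
window_trial <- function(trial, events, pre_ms = 100, post_ms = 100) {
  if (events$td_s <= events$bon_s) stop("touchdown must come after belt onset")
  start_s <- events$bon_s - pre_ms / 1000
  end_s <- events$td_s + post_ms / 1000
  if (start_s < 0) stop(sprintf("window starts %.3f s before the trial", -start_s))
  n <- ncol(trial$signal)
  i0 <- floor(start_s * trial$rate_hz + 1e-9) + 1L
  i1 <- floor(end_s * trial$rate_hz + 1e-9)        # end exclusive
  if (i1 > n) stop(sprintf("window ends %.3f s past the trial",
                           end_s - n / trial$rate_hz))
  if (i1 < i0 + 1L) stop("empty analysis window")
  emg_trial(trial$signal[, i0:i1, drop = FALSE], trial$rate_hz,
            trial$trial_id, trial$stage)
}

#' Binned activation matrix
#'
#' Container for the muscle-by-timebin pattern matrix M that synergy
#' extraction factorizes: 8 rows in canonical channel order, one column per
#' time bin.
#'
#' @param values Non-negative 8 x n_bins matrix.
#' @param bin_ms Bin width, milliseconds.
#' @param trial_boundaries First-bin index (1-based) of each concatenated trial.
#' @param norm_factors Per-muscle maxima used by [normalize_max()], if applied.
#' @param unit_var_scales Per-muscle standard deviations removed by
#'   [scale_unit_variance()], if applied.
#' @export
envelope_matrix <- function(values, bin_ms, trial_boundaries = 1L,
                            norm_factors = NULL, unit_var_scales = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != 8L) stop("envelope matrix must have 8 rows")
  if (any(values < 0)) stop("envelope matrix must be non-negative")
  rownames(values) <- canonical_channels()
  structure(
    list(values = values, bin_ms = bin_ms, muscle_order = canonical_channels(),
         trial_boundaries = as.integer(trial_boundaries),
         norm_factors = norm_factors, unit_var_scales = unit_var_scales),
    class = "envelope_matrix")
}

#' @export
print.envelope_matrix <- function(x, ...) {
  cat(sprintf("<envelope_matrix> 8 muscles x %d bins of %g ms (%d trial block%s)\n",
              ncol(x$values), x$bin_ms, length(x$trial_boundaries),
              if (length(x$trial_boundaries) == 1) "" else "s"))
  invisible(x)
}

#' Down-sample an envelope into fixed-width time bins
#'
#' Each bin holds the mean of the samples whose start times fall inside it;
#' a trailing partial bin is dropped rather than padded.
#'
#' @param trial Enveloped [emg_trial()].
#' @param bin_ms Bin width, milliseconds (default 10).
#' @return An [envelope_matrix()].
#' @export
bin_average <- function(trial, bin_ms = 10) {
  n <- ncol(trial$signal)
  bin_s <- bin_ms / 1000
  t_start <- (seq_len(n) - 1L) / trial$rate_hz
  idx <- floor(t_start / bin_s + 1e-9)
  n_bins <- floor(n / trial$rate_hz / bin_s + 1e-9)
  if (n_bins < 1) stop("trial shorter than one bin")
  keep <- idx < n_bins
  g <- factor(idx[keep], levels = 0:(n_bins - 1))
  counts <- as.integer(table(g))
  sums <- t(rowsum(t(trial$signal[, keep, drop = FALSE]), g))
  vals <- sweep(sums, 2, counts, "/")
  envelope_matrix(pmax(vals, 0), bin_ms)
}

#' Concatenate per-trial envelope matrices end-to-end
#'
#' Joins the binned envelopes of a stage's consecutive trials into one
#' matrix, recording where each trial's block starts.
#'
#' @param mats List of [envelope_matrix()] with identical bin width.
#' @return Concatenated [envelope_matrix()].
#' @export
concatenate_envelopes <- function(mats) {
  if (!length(mats)) stop("nothing to concatenate")
  bw <- unique(vapply(mats, function(m) m$bin_ms, 1))
  if (length(bw) != 1) stop("bin widths differ across trials")
  orders <- vapply(mats, function(m) paste(m$muscle_order, collapse = ","), "")
  if (length(unique(orders)) != 1) stop("muscle order differs across trials")
  widths <- vapply(mats, function(m) ncol(m$values), 1L)
  boundaries <- cumsum(c(1L, widths[-length(widths)]))
  envelope_matrix(do.call(cbind, lapply(mats, function(m) m$values)),
                  bw, trial_boundaries = boundaries)
}

#' Maximum-activation normalization
#'
#' Divides each muscle row by its maximum activation. By protocol the
#' factors come from the participant's full session (all trials), so the
#' same scaling applies to the early and late stage blocks and amplitudes
#' stay comparable across stages; pass these via `norm_factors`.
#'
#' @param m An [envelope_matrix()].
#' @param norm_factors Optional per-muscle maxima (length 8). Default: each
#'   row's own maximum.
#' @return Normalized [envelope_matrix()] with factors stored.
#' @export
normalize_max <- function(m, norm_factors = NULL) {
  if (is.null(norm_factors)) {
    norm_factors <- apply(m$values, 1, max)
  }
  if (length(norm_factors) != 8) stop("need 8 per-muscle normalization factors")
  zero <- norm_factors <= 0
  if (any(zero)) {
    stop("zero maximum activation for muscle(s): ",
         paste(m$muscle_order[zero], collapse = ", "))
  }
  envelope_matrix(m$values / norm_factors, m$bin_ms, m$trial_boundaries,
                  norm_factors = as.numeric(norm_factors),
                  unit_var_scales = m$unit_var_scales)
}

#' Per-muscle maxima across a set of envelope matrices
#'
#' Computes the session-wide normalization factors: each muscle's maximum
#' over all supplied (windowed, binned) trials.
#'
#' @param mats List of [envelope_matrix()].
#' @return Numeric vector of length 8.
#' @export
max_norm_factors <- function(mats) {
  apply(do.call(cbind, lapply(mats, function(m) m$values)), 1, max)
}

#' Unit-variance scaling of muscle rows
#'
#' Divides each muscle row by its sample standard deviation (n - 1
#' denominator) so every muscle carries equal weight in the factorization.
#' The removed scales are stored so [unscale_and_normalize()] can restore
#' the original row scaling of the extracted synergy vectors afterwards.
#'
#' @param m An [envelope_matrix()].
#' @return Scaled [envelope_matrix()] with `unit_var_scales` set.
#' @export
scale_unit_variance <- function(m) {
  sds <- apply(m$values, 1, stats::sd)
  zero <- sds <= 0 | !is.finite(sds)
  if (any(zero)) {
    stop("zero-variance muscle row(s): ",
         paste(m$muscle_order[zero], collapse = ", "))
  }
  envelope_matrix(m$values / sds, m$bin_ms, m$trial_boundaries,
                  norm_factors = m$norm_factors,
                  unit_var_scales = as.numeric(sds))
}

#' Full preprocessing chain for one stage of a session
#'
#' Runs envelope -> window -> bin on every trial, concatenates the stage's
#' trials, normalizes by the supplied session-wide per-muscle maxima and
#' applies unit-variance scaling — the fixed order the analysis prescribes.
#'
#' @param trials List of raw [emg_trial()] for the stage, in trial order.
#' @param events List of per-trial event lists (`bon_s`, `td_s`).
#' @param norm_factors Session-wide per-muscle maxima (see [max_norm_factors()]).
#' @param cfg A [pipeline_config()].
#' @return Preprocessed [envelope_matrix()] ready for synergy extraction.
#' @export
preprocess_stage <- function(trials, events, norm_factors, cfg = pipeline_config()) {
  mats <- mapply(function(tr, ev) {
    env <- emg_envelope(tr, cfg$emg_hp_hz, cfg$emg_lp_hz)
    bin_average(window_trial(env, ev, cfg$pre_ms, cfg$post_ms), cfg$bin_ms)
  }, trials, events, SIMPLIFY = FALSE)
  scale_unit_variance(normalize_max(concatenate_envelopes(mats), norm_factors))
}
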