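#' Time-normalize an activation curve to a fixed number of points
#'
#' Linear interpolation onto `n_out` equally spaced points spanning the full
#' duration (endpoints preserved), so activation curves from responses of
#' different duration can be averaged and compared. The analysis convention
#' is 100 points spanning the belt-onset-minus-100 ms to
#' touchdown-plus-100 ms window.
#'
#' @param x Numeric activation vector (length at least 2).
#' @param n_out Output length (default 100).
#' @return Numeric vector of length `n_out`.
#' @export
time_normalize <- function(x, n_out = 100) {
  if (length(x) < 2) stop("need at least 2 samples to time-normalize")
  stats::approx(seq(0, 1, length.out = length(x)), x,
                xout = seq(0, 1, length.out = n_out))$y
}

#' Activation onset time
#'
#' First instant at which the activation strictly exceeds `frac_pct`% of its
#' peak, as a percent of the curve's span. Returns 0 when the curve starts
#' above threshold and `NA` for an all-zero curve (onset undefined; such
#' values are excluded from onset statistics downstream).
#'
#' @param curve Numeric activation curve.
#' @param frac_pct Threshold, percent of peak (default 25).
#' @return Onset as percent of span, or `NA_real_`.
#' @export
onset_time <- function(curve, frac_pct = 25) {
  pk <- max(curve)
  if (pk <= 0) return(NA_real_)
  idx <- which(curve > frac_pct / 100 * pk)
  if (!length(idx)) return(NA_real_)
  (idx[1] - 1) / (length(curve) - 1) * 100
}

#' Peak and area of an activation curve
#'
#' Peak amplitude and its time (percent of span, first index on ties), and
#' the area under the curve by the trapezoidal rule over a normalized time
#' axis running 0..100 (units: activation x percent-span).
#'
#' @param curve Numeric activation curve.
#' @return List with `peak_amp`, `peak_time_pct`, `area`.
#' @export
peak_and_area <- function(curve) {
  n <- length(curve)
  if (n < 2) stop("need at least 2 samples")
  pk <- which.max(curve)
  dx <- 100 / (n - 1)
  area <- sum((curve[-1] + curve[-n]) / 2) * dx
  list(peak_amp = curve[pk], peak_time_pct = (pk - 1) / (n - 1) * 100,
       area = area)
}

#' All temporal features of one activation curve
#'
#' @param curve Activation curve (any length; time-normalized to
#'   `n_out` points first).
#' @param onset_frac_pct Onset threshold, percent of peak.
#' @param n_out Points in the normalized curve.
#' @return List with `peak_amp`, `peak_time_pct`, `area`, `onset_pct`,
#'   `curve100`.
#' @export
activation_features <- function(curve, onset_frac_pct = 25, n_out = 100) {
  c100 <- time_normalize(curve, n_out)
  pa <- peak_and_area(c100)
  c(pa, list(onset_pct = onset_time(c100, onset_frac_pct), curve100 = c100))
}

feature_names <- function() c("peak_amp", "area", "peak_time_pct", "onset_pct")

#' Paired comparison of activation features across stages
#'
#' Pairs per-participant feature values for one mode between the early and
#' late stages and runs a dependent t-test with paired Cohen's d per
#' feature. Participants with an undefined onset in either stage are
#' dropped from the onset comparison only.
#'
#' @param early,late Data frames with a `participant` column and columns
#'   `peak_amp`, `area`, `peak_time_pct`, `onset_pct`.
#' @return Data frame: `feature`, `n_pairs`, `mean_early`, `mean_late`,
#'   `t`, `df`, `p`, `d`.
#' @export
compare_features <- function(early, late) {
  common <- intersect(early$participant, late$participant)
  if (length(common) < 3) stop("fewer than 3 paired participants")
  e <- early[match(common, early$participant), ]
  l <- late[match(common, late$participant), ]
  rows <- lapply(feature_names(), function(f) {
    ok <- stats::complete.cases(e[[f]], l[[f]])
    if (sum(ok) < 3) stop("fewer than 3 defined pairs for feature ", f)
    res <- paired_t(e[[f]][ok], l[[f]][ok])
    data.frame(feature = f, n_pairs = sum(ok),
               mean_early = mean(e[[f]][ok]), mean_late = mean(l[[f]][ok]),
               t = res$statistic, df = res$df, p = res$p,
               d = res$effect_size_d, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
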