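#' Extract muscle synergies by non-negative matrix factorization
#'
#' Factorizes the preprocessed activation matrix M (8 muscles x n time bins)
#' as M ~ W C + eps, where the columns of W are non-negative, time-invariant
#' muscle synergy vectors and the rows of C are their non-negative
#' activation coefficients over time. Fitting minimizes the squared
#' Frobenius reconstruction error with Lee-Seung multiplicative updates
#' (monotone in the objective), restarted from `restarts` uniform-random
#' non-negative initializations; the best run by residual norm is kept.
#'
#' When `k` is `NULL` the dimensionality is selected as the smallest number
#' of synergies satisfying all three criteria: global VAF above
#' `cfg$vaf_global_pct` (90%), every per-muscle VAF above
#' `cfg$vaf_muscle_pct` (75%), and adding one more synergy raising the mean
#' per-muscle VAF by at most `cfg$vaf_gain_pct` (5) percentage points
#' (vacuously true at `k_max`).
#'
#' @param m An [envelope_matrix()] (non-negative).
#' @param k Number of synergies, or `NULL` to select automatically.
#' @param cfg A [pipeline_config()] supplying restarts, iteration cap,
#'   tolerance and the selection thresholds.
#' @param seed Integer seed making the random restarts reproducible.
#' @param trace Record the objective at every iteration of the winning run
#'   (used to audit monotone convergence).
#' @return An object of class `synergy_fit` with elements `W` (8 x K), `C`
#'   (K x n), `K`, `vaf_global`, `vaf_muscle`, `restarts_used`, `seed`,
#'   and, for automatic selection, `diagnostics` holding the VAF curve of
#'   every candidate dimensionality.
#' @seealso [vaf_global()], [vaf_muscle()], [unscale_and_normalize()]
#' @export
extract_synergies <- function(m, k = NULL, cfg = pipeline_config(),
                              seed = cfg$seed, trace = FALSE) {
  if (!is.null(k)) {
    return(nnmf_fit(m, k, restarts = cfg$nnmf_restarts,
                    max_iter = cfg$nnmf_max_iter, tol = cfg$nnmf_tol,
                    seed = seed, trace = trace))
  }
  select_dimensionality(m, cfg = cfg, seed = seed)
}

#' @rdname extract_synergies
#' @param restarts,max_iter,tol Factorization controls (see [pipeline_config()]).
#' @export
nnmf_fit <- function(m, k, restarts = 20, max_iter = 2000, tol = 1e-6,
                     seed = 1L, trace = FALSE) {
  V <- m$values
  n <- ncol(V)
  if (k < 1 || k > min(8, n)) stop("k must be between 1 and min(8, n_bins)")
  if (all(V == 0)) stop("cannot factorize an all-zero matrix")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    W0 <- matrix(stats::runif(8 * k), 8, k)
    H0 <- matrix(stats::runif(k * n), k, n)
    res <- .nnmf_mu(V, W0, H0, as.integer(max_iter), tol, trace)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  W <- best$W
  C <- best$H
  rownames(W) <- canonical_channels()
  colnames(W) <- paste0("syn", seq_len(k))
  rownames(C) <- colnames(W)
  fit <- structure(
    list(W = W, C = C, K = k, m = m,
         objective = best$objective,
         vaf_global = vaf_from_residual(V, W %*% C),
         vaf_muscle = vaf_muscle_rows(V, W %*% C),
         restarts_used = restarts, seed = seed,
         converged = best$converged, iterations = best$iterations,
         objective_trace = best$trace,
         diagnostics = NULL),
    class = "synergy_fit")
  fit
}

vaf_from_residual <- function(V, R) {
  ss <- sum(V^2)
  if (ss == 0) stop("VAF undefined for an all-zero matrix")
  100 * (1 - sum((V - R)^2) / ss)
}

vaf_muscle_rows <- function(V, R) {
  ss <- rowSums(V^2)
  if (any(ss == 0)) {
    stop("VAF undefined for all-zero muscle row(s): ",
         paste(rownames(V)[ss == 0], collapse = ", "))
  }
  stats::setNames(100 * (1 - rowSums((V - R)^2) / ss), rownames(V))
}

#' Variance accounted for by a synergy reconstruction
#'
#' Uncentered VAF, the convention of the synergy literature:
#' `100 * (1 - ||M - WC||^2_F / ||M||^2_F)`, i.e. the percent of raw signal
#' energy (not deviations from the mean) captured by the reconstruction.
#'
#' @param m An [envelope_matrix()].
#' @param fit A `synergy_fit`.
#' @return Percent (at most 100; negative when the reconstruction is worse
#'   than predicting zero).
#' @export
vaf_global <- function(m, fit) vaf_from_residual(m$values, fit$W %*% fit$C)

#' @rdname vaf_global
#' @return `vaf_muscle`: named vector of 8 per-muscle percents.
#' @export
vaf_muscle <- function(m, fit) vaf_muscle_rows(m$values, fit$W %*% fit$C)

#' @rdname extract_synergies
#' @param k_max Largest dimensionality tried.
#' @export
select_dimensionality <- function(m, k_max = cfg$k_max, cfg = pipeline_config(),
                                  seed = cfg$seed) {
  k_max <- min(k_max, 8, ncol(m$values))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, k_max)
  fits <- vector("list", k_max)
  fit_at <- function(k) {
    if (is.null(fits[[k]])) {
      fits[[k]] <<- nnmf_fit(m, k, restarts = cfg$nnmf_restarts,
                             max_iter = cfg$nnmf_max_iter, tol = cfg$nnmf_tol,
                             seed = sub_seeds[k])
    }
    fits[[k]]
  }
  chosen <- NA_integer_
  for (k in seq_len(k_max)) {
    f <- fit_at(k)
    if (f$vaf_global <= cfg$vaf_global_pct) next
    if (any(f$vaf_muscle <= cfg$vaf_muscle_pct)) next
    if (k < k_max) {
      gain <- mean(fit_at(k + 1)$vaf_muscle) - mean(f$vaf_muscle)
      if (gain > cfg$vaf_gain_pct) next
    }
    chosen <- k
    break
  }
  computed <- which(!vapply(fits, is.null, TRUE))
  curve <- data.frame(
    k = computed,
    vaf_global = vapply(computed, function(k) fits[[k]]$vaf_global, 1),
    vaf_muscle_min = vapply(computed, function(k) min(fits[[k]]$vaf_muscle), 1),
    vaf_muscle_mean = vapply(computed, function(k) mean(fits[[k]]$vaf_muscle), 1))
  if (is.na(chosen)) {
    cond <- simpleError(
      sprintf("no dimensionality up to %d meets the VAF criteria (best global VAF %.1f%%, best worst-muscle VAF %.1f%%)",
              k_max, max(curve$vaf_global), max(curve$vaf_muscle_min)))
    attr(cond, "vaf_curve") <- curve
    stop(cond)
  }
  fit <- fits[[chosen]]
  fit$diagnostics <- list(vaf_curve = curve,
                          candidates = fits[computed])
  fit
}

#' Restore original scaling and unit-max normalize a synergy set
#'
#' Undoes the unit-variance preprocessing by multiplying each muscle row of
#' W by the standard deviation that was removed, returning the synergy
#' vectors to the original (max-normalized) activation scale. Each synergy
#' column is then rescaled to unit maximum, with the reciprocal applied to
#' its activation row so the reconstruction W C is unchanged by this second
#' step.
#'
#' @param fit A `synergy_fit`.
#' @param unit_var_scales Per-muscle standard deviations removed before
#'   extraction (stored on the [envelope_matrix()] by
#'   [scale_unit_variance()]); defaults to those of the fitted matrix.
#' @return The rescaled `synergy_fit` (fields `W`, `C` replaced;
#'   `unit_max = TRUE`).
#' @export
unscale_and_normalize <- function(fit, unit_var_scales = fit$m$unit_var_scales) {
  if (is.null(unit_var_scales)) stop("no unit-variance scales available")
  if (length(unit_var_scales) != 8 || any(unit_var_scales <= 0)) {
    stop("unit_var_scales must be 8 positive numbers")
  }
  W <- fit$W * unit_var_scales
  mx <- apply(W, 2, max)
  if (any(mx <= 0)) stop("synergy column with non-positive maximum")
  fit$W <- sweep(W, 2, mx, "/")
  fit$C <- sweep(fit$C, 1, mx, "*")
  fit$unit_max <- TRUE
  fit
}

#' @export
print.synergy_fit <- function(x, ...) {
  cat(sprintf("<synergy_fit> K = %d synergies over %d bins; global VAF %.1f%% (muscle VAF %.1f-%.1f%%)\n",
              x$K, ncol(x$C), x$vaf_global, min(x$vaf_muscle), max(x$vaf_muscle)))
  invisible(x)
}

#' @export
summary.synergy_fit <- function(object, ...) {
  out <- list(K = object$K, vaf_global = object$vaf_global,
              vaf_muscle = object$vaf_muscle, W = object$W,
              restarts_used = object$restarts_used,
              converged = object$converged,
              vaf_curve = object$diagnostics$vaf_curve)
  class(out) <- "summary.synergy_fit"
  out
}

#' @export
print.summary.synergy_fit <- function(x, ...) {
  cat(sprintf("Muscle synergy factorization: K = %d\n", x$K))
  cat(sprintf("Global VAF: %.2f%%; per-muscle VAF:\n", x$vaf_global))
  print(round(x$vaf_muscle, 2))
  cat("Synergy vectors (W):\n")
  print(round(x$W, 3))
  if (!is.null(x$vaf_curve)) {
    cat("Dimensionality search:\n")
    print(x$vaf_curve, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.synergy_fit <- function(object, ...) list(W = object$W, C = object$C)

#' @export
fitted.synergy_fit <- function(object, ...) object$W %*% object$C

#' @export
residuals.synergy_fit <- function(object, ...) object$m$values - fitted(object)

#' @export
plot.synergy_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(x$K, 2), mar = c(2.5, 3.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  for (i in seq_len(x$K)) {
    graphics::barplot(x$W[, i], las = 2, cex.names = 0.7,
                      main = sprintf("W%d", i), col = "grey40", ...)
    graphics::plot(x$C[i, ], type = "l", xlab = "", ylab = sprintf("C%d", i), ...)
  }
  invisible(x)
}
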