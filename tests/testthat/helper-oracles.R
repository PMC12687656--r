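# Independent oracles and small fixture builders used across the suite.

# Greedy max-cosine matching of recovered to true synergy columns; returns
# the matched cosines (descending pick order).
cos_match <- function(What, Wtrue) {
  Wh <- sweep(What, 2, sqrt(colSums(What^2)), "/")
  Wt <- sweep(Wtrue, 2, sqrt(colSums(Wtrue^2)), "/")
  S <- t(Wh) %*% Wt
  out <- numeric(0)
  for (i in seq_len(min(dim(S)))) {
    ij <- arrayInd(which.max(S), dim(S))
    out <- c(out, S[ij])
    S[ij[1], ] <- -2
    S[, ij[2]] <- -2
  }
  out
}

# Brute-force Pearson correlation from first principles.
pearson_oracle <- function(a, b) {
  sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all sign patterns.
wilcoxon_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# Repeated-measures one-way ANOVA F by explicit sums of squares.
rm_anova_oracle <- function(values) {
  n <- nrow(values); cc <- ncol(values)
  grand <- mean(values)
  ss_cond <- n * sum((colMeans(values) - grand)^2)
  ss_subj <- cc * sum((rowMeans(values) - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f <- (ss_cond / (cc - 1)) / (ss_err / ((cc - 1) * (n - 1)))
  list(F = f, p = stats::pf(f, cc - 1, (cc - 1) * (n - 1), lower.tail = FALSE))
}

# Paired t statistic from first principles.
paired_t_oracle <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), n - 1))
}

# An 8 x n envelope matrix from given row values (recycled).
make_env <- function(values, bin_ms = 10) {
  envelope_matrix(values, bin_ms = bin_ms)
}

# Small raw EMG trial with every channel equal to `x`.
flat_emg <- function(x, rate_hz = 600) {
  emg_trial(matrix(rep(x, each = 8), 8, byrow = FALSE), rate_hz)
}

# Minimal marker trial: named markers at fixed positions, n frames.
static_markers <- function(positions, n_frames = 240, rate_hz = 120) {
  nm <- names(positions)
  pos <- array(NA_real_, c(length(nm), n_frames, 3))
  for (i in seq_along(nm)) pos[i, , ] <- matrix(positions[[i]], n_frames, 3, byrow = TRUE)
  marker_trial(pos, nm, rate_hz)
}

# Default standing posture for constructed kinematics cases (all required
# markers present).
base_posture <- function() {
  list(BELT = c(0.3, -0.4, 0),
       L_HEEL = c(0, 0.1, 0.02), R_HEEL = c(0, -0.1, 0.02),
       L_TOE = c(0.25, 0.1, 0.02), R_TOE = c(0.25, -0.1, 0.02),
       L_SHOULDER = c(0, 0.18, 1.4), R_SHOULDER = c(0, -0.18, 1.4),
       L_HIP = c(0, 0.09, 0.9), R_HIP = c(0, -0.09, 0.9),
       L_ELBOW = c(0, 0.2, 1.1), R_ELBOW = c(0, -0.2, 1.1),
       L_KNEE = c(0, 0.1, 0.48), R_KNEE = c(0, -0.1, 0.48),
       L_WRIST = c(0, 0.21, 0.85), R_WRIST = c(0, -0.21, 0.85),
       HEAD = c(0, 0, 1.6))
}

# Construct a clustered_modes object directly (for naming/matching tests).
fake_modes <- function(centroids, assignments, pooled, participants,
                       stage = "early", names = NULL) {
  k <- ncol(centroids)
  rownames(centroids) <- canonical_channels()
  structure(
    list(stage = stage, centroids = centroids, assignments = assignments,
         provenance = data.frame(participant = participants,
                                 synergy = seq_along(participants)),
         pooled = pooled, silhouette_by_k = NULL, chosen_k = k,
         mode_names = names %||% paste0("mode", seq_len(k)),
         mode_order = seq_len(k), activation = NULL),
    class = "clustered_modes")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
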