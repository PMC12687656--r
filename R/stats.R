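#' Statistical test result container
#'
#' Uniform return type for the pipeline's statistical toolbox.
#'
#' @param test Test name.
#' @param statistic Test statistic (t, V, F, D or r).
#' @param df Degrees of freedom (possibly two for F).
#' @param p Two-tailed p value.
#' @param effect_size_d Paired Cohen's d (dz), where applicable.
#' @param n Sample size used.
#' @export
stats_result <- function(test, statistic, df = NA_real_, p = NA_real_,
                         effect_size_d = NULL, n = NA_integer_) {
  structure(list(test = test, statistic = unname(statistic), df = unname(df),
                 p = unname(p), effect_size_d = unname(effect_size_d), n = n),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g%s\n", x$test,
              x$statistic, paste(signif(x$df, 4), collapse = ","), x$p,
              if (!is.null(x$effect_size_d)) sprintf(", d = %.3f", x$effect_size_d) else ""))
  invisible(x)
}

#' Lilliefors-corrected Kolmogorov-Smirnov normality test
#'
#' One-sample KS test against a normal distribution with mean and standard
#' deviation estimated from the sample, with the Lilliefors correction of
#' the p value (a naive KS test with fitted parameters is anti-conservative).
#'
#' @param x Numeric sample (n of at least 5, non-constant).
#' @return A [stats_result()].
#' @export
ks_normality <- function(x) {
  if (length(x) < 5) stop("normality test needs at least 5 observations")
  if (stats::sd(x) == 0) stop("normality test undefined for a constant sample")
  res <- nortest::lillie.test(x)
  stats_result("ks", res$statistic, df = length(x), p = res$p.value,
               n = length(x))
}

#' Paired-samples t-test with paired Cohen's d
#'
#' Two-tailed dependent t-test on the differences `x - y`;
#' `t = mean(d) / (sd(d)/sqrt(n))` with `n - 1` degrees of freedom. The
#' effect size is the paired Cohen's d (dz), `mean(d)/sd(d)`.
#'
#' @param x,y Paired numeric samples of equal length.
#' @return A [stats_result()].
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  n <- length(x)
  if (n < 2) stop("paired t-test needs at least 2 pairs")
  d <- x - y
  if (all(d == 0)) {
    return(stats_result("paired_t", 0, df = n - 1, p = 1, effect_size_d = 0, n = n))
  }
  if (stats::sd(d) == 0) {
    stop("degenerate paired input: constant nonzero differences")
  }
  res <- stats::t.test(x, y, paired = TRUE)
  stats_result("paired_t", res$statistic, df = res$parameter, p = res$p.value,
               effect_size_d = mean(d) / stats::sd(d), n = n)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped and ties mid-ranked; the p value is exact
#' for 25 or fewer untied nonzero pairs and uses the continuity-corrected
#' normal approximation otherwise.
#'
#' @param x,y Paired numeric samples of equal length.
#' @return A [stats_result()].
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired samples must have equal length")
  d <- x - y
  nz <- d[d != 0]
  if (!length(nz)) {
    return(stats_result("wilcoxon", 0, p = 1, n = length(x)))
  }
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  res <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = exact, correct = TRUE))
  stats_result("wilcoxon", res$statistic, p = res$p.value, n = length(x))
}

#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way ANOVA: `F = MS_condition / MS_(condition x
#' subject)` with `(c - 1, (c - 1)(n - 1))` degrees of freedom and no
#' sphericity correction. Fitted through [stats::aov()] with a subject
#' error stratum.
#'
#' @param values Numeric matrix, participants in rows, conditions in
#'   columns; no missing cells.
#' @return A [stats_result()] with `df = c(df1, df2)`.
#' @export
rm_anova <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("repeated-measures ANOVA requires complete cells")
  n <- nrow(values); cc <- ncol(values)
  if (n < 2 || cc < 2) stop("need at least 2 participants and 2 conditions")
  df <- data.frame(y = as.vector(values),
                   subject = factor(rep(seq_len(n), cc)),
                   condition = factor(rep(seq_len(cc), each = n)))
  fit <- stats::aov(y ~ condition + Error(subject), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fv <- tab["condition", "F value"]
  p <- tab["condition", "Pr(>F)"]
  # numerically zero condition effect (identical conditions per subject)
  if (is.na(Fv) || tab["condition", "Sum Sq"] < 1e-12 * max(sum(values^2), 1)) {
    Fv <- 0; p <- 1
  }
  stats_result("rm_anova", Fv, df = c(cc - 1, (cc - 1) * (n - 1)), p = p, n = n)
}

#' Pearson correlation between two vectors
#'
#' @param a,b Numeric vectors of equal length (at least 3 points,
#'   non-constant).
#' @return A [stats_result()] with `df = n - 2`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3) stop("correlation needs at least 3 points")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a zero-variance vector")
  }
  res <- stats::cor.test(a, b, method = "pearson")
  stats_result("pearson", res$estimate, df = res$parameter, p = res$p.value,
               n = length(a))
}

#' Two-tailed critical value of the Pearson correlation
#'
#' The smallest |r| significant at level `alpha` with `df = n - 2` degrees
#' of freedom: `r* = t* / sqrt(t*^2 + df)` with `t*` the `1 - alpha/2`
#' Student-t quantile. With `alpha = 0.01` and `df = 6` (8 muscle weights)
#' this gives 0.83 to two decimals — the threshold used to class cross-stage
#' mode similarity.
#'
#' @param alpha Two-tailed significance level.
#' @param df Degrees of freedom (n - 2).
#' @return Critical r in [0, 1).
#' @export
critical_r <- function(alpha, df) {
  if (df < 1) stop("df must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  tstar <- stats::qt(1 - alpha / 2, df)
  tstar / sqrt(tstar^2 + df)
}
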