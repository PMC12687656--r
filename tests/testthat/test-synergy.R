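test_that("factorization recovers an exact rank-1 matrix and stays non-negative", {
  w <- c(1, 2, 0, 0, 0, 0, 0, 0)
  M <- make_env(pmax(outer(w, c(1, 2, 3, 4)), 1e-6))
  fit <- nnmf_fit(M, k = 1, restarts = 5, seed = 2)
  expect_gte(fit$vaf_global, 99.9)
  expect_true(all(fit$W >= 0) && all(fit$C >= 0))

  fit2 <- nnmf_fit(M, k = 1, restarts = 5, seed = 2)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$C, fit2$C)

  expect_error(nnmf_fit(M, k = 0), "between 1")
  expect_error(nnmf_fit(make_env(matrix(1e-3, 8, 4) * 0 + 0), k = 1), "all-zero")
})

test_that("objective is monotone over iterations and VAF non-decreasing in K", {
  set.seed(8)
  M <- make_env(matrix(abs(rnorm(8 * 60)), 8))
  fit <- nnmf_fit(M, k = 3, restarts = 3, seed = 4, trace = TRUE)
  expect_true(all(diff(fit$objective_trace) <= 1e-10))

  vafs <- vapply(1:5, function(k) nnmf_fit(M, k, restarts = 20, seed = 5)$vaf_global, 1)
  expect_true(all(diff(vafs) >= -0.5))
})

test_that("VAF definitions match direct arithmetic", {
  M <- make_env(matrix(1, 8, 2))
  # K = 2 lets W C reproduce M exactly except one zeroed cell
  R <- matrix(1, 8, 2); R[2, 2] <- 0
  fit <- structure(list(W = R, C = diag(2), K = 2, m = M), class = "synergy_fit")
  expect_equal(vaf_global(M, fit), 100 * (1 - 1 / 16))
  vm <- vaf_muscle(M, fit)
  expect_equal(unname(vm[2]), 100 * (1 - 1 / 2))
  expect_equal(unname(vm[1]), 100)

  # row [3,4] reconstructed as [3,0] -> 36%
  M2v <- matrix(1, 8, 2); M2v[1, ] <- c(3, 4)
  R2 <- M2v; R2[1, 2] <- 0
  fit2 <- structure(list(W = R2, C = diag(2), K = 2, m = make_env(M2v)),
                    class = "synergy_fit")
  expect_equal(unname(vaf_muscle(make_env(M2v), fit2)[1]), 36)

  # mean per-muscle VAF need not equal global VAF (rows of unequal norm)
  expect_false(isTRUE(all.equal(mean(vaf_muscle(make_env(M2v), fit2)),
                                vaf_global(make_env(M2v), fit2))))

  # exact reconstruction
  fit3 <- structure(list(W = M2v, C = diag(2), K = 2), class = "synergy_fit")
  expect_equal(vaf_global(make_env(M2v), fit3), 100)
})

test_that("dimensionality selection applies the three VAF criteria", {
  # exact non-negative rank 1: all criteria met at K = 1
  M <- make_env(outer(c(1, 2, 1, 3, 2, 1, 2, 1), c(1, 2, 3, 4, 2)))
  sel <- select_dimensionality(M, cfg = pipeline_config(nnmf_restarts = 5), seed = 3)
  expect_equal(sel$K, 1)
  expect_s3_class(sel$diagnostics$vaf_curve, "data.frame")

  # well-separated planted synergies at modest noise: K = 3 recovered
  set.seed(12)
  ks <- integer(5)
  for (r in 1:5) {
    W <- matrix(0.05, 8, 3)
    W[1:2, 1] <- c(1, 0.6); W[4:5, 2] <- c(1, 0.7); W[7:8, 3] <- c(0.8, 1)
    pct <- seq(0, 100, length.out = 60)
    C <- t(vapply(c(25, 50, 75),
                  function(p) exp(-(pct - p)^2 / 50) + 0.02, numeric(60)))
    M3 <- W %*% C
    M3 <- pmax(M3 + matrix(rnorm(length(M3), 0, 0.05 * mean(M3)), 8), 1e-6)
    sel3 <- select_dimensionality(make_env(M3),
                                  cfg = pipeline_config(nnmf_restarts = 10),
                                  seed = 100 + r)
    ks[r] <- sel3$K
  }
  expect_true(all(ks == 3))

  # iid noise never reaches the per-muscle criterion at small k_max
  set.seed(13)
  Mn <- make_env(matrix(runif(8 * 80), 8))
  err <- tryCatch(select_dimensionality(Mn, k_max = 2,
                                        cfg = pipeline_config(nnmf_restarts = 5),
                                        seed = 6),
                  error = function(e) e)
  expect_s3_class(err, "error")
  expect_s3_class(attr(err, "vaf_curve"), "data.frame")
})

test_that("unscale_and_normalize restores row scaling without changing the fit", {
  set.seed(9)
  vals <- matrix(abs(rnorm(8 * 40)) + 0.1, 8)
  m0 <- normalize_max(make_env(vals))
  ms <- scale_unit_variance(m0)
  fit <- nnmf_fit(ms, k = 2, restarts = 5, seed = 7)
  rec_scaled <- fit$W %*% fit$C
  out <- unscale_and_normalize(fit)
  # reconstruction in original units equals sds * scaled reconstruction
  expect_equal(out$W %*% out$C, ms$unit_var_scales * rec_scaled,
               tolerance = 1e-9)
  expect_equal(unname(apply(out$W, 2, max)), rep(1, 2), tolerance = 1e-12)

  # scales of 1: only the unit-max normalization applies
  out1 <- unscale_and_normalize(fit, unit_var_scales = rep(1, 8))
  expect_equal(out1$W, sweep(fit$W, 2, apply(fit$W, 2, max), "/"), tolerance = 1e-12)

  expect_error(unscale_and_normalize(fit, unit_var_scales = c(rep(1, 7), -1)),
               "positive")
})

test_that("planted synergy vectors are recovered with high cosine similarity", {
  # K = 4 planted synergies, 100 bins, 10% envelope noise
  set.seed(14)
  cosines <- numeric(20)
  for (r in 1:20) {
    W <- matrix(runif(8 * 4, 0, 0.3), 8)
    W[cbind(c(1, 3, 5, 7), 1:4)] <- 1
    pct <- seq(0, 100, length.out = 100)
    C <- t(vapply(c(20, 40, 60, 80),
                  function(p) exp(-(pct - p)^2 / 50) + 0.02, numeric(100)))
    M <- W %*% C
    M <- pmax(M + matrix(rnorm(length(M), 0, 0.10 * mean(M)), 8), 1e-6)
    fit <- nnmf_fit(make_env(M), k = 4, restarts = 20, seed = 200 + r)
    cosines[r] <- mean(cos_match(fit$W, W))
  }
  expect_gte(mean(cosines), 0.95)
})
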