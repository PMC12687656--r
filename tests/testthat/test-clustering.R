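make_fit <- function(W, id) {
  structure(list(W = W, C = matrix(1, ncol(W), 4), K = ncol(W)),
            class = "synergy_fit")
}

test_that("pooling stacks unit-max synergies with provenance", {
  W2 <- matrix(runif(16), 8); W3 <- matrix(runif(24), 8)
  fits <- list(A = make_fit(W2), B = make_fit(W3))
  pooled <- pool_synergies(fits)
  expect_equal(ncol(pooled$X), 5)
  expect_equal(pooled$provenance$participant, c("A", "A", "B", "B", "B"))
  expect_equal(pooled$provenance$synergy, c(1L, 2L, 1L, 2L, 3L))
  expect_equal(unname(pooled$X[, 3]), unname(W3[, 1]))
  expect_error(pool_synergies(list()), "no synergy")
})

test_that("k-means recovers planted groups and is deterministic", {
  set.seed(20)
  c1 <- c(1, 0, 0, 0, 1, 0, 0, 0); c2 <- c(0, 0, 1, 1, 0, 0, 1, 0)
  X <- cbind(matrix(c1, 8, 10) + matrix(rnorm(80, 0, 0.02), 8),
             matrix(c2, 8, 10) + matrix(rnorm(80, 0, 0.02), 8))
  cl <- kmeans_synergies(X, 2, n_init = 20, seed = 3)
  expect_equal(length(unique(cl$assignments[1:10])), 1)
  expect_equal(length(unique(cl$assignments[11:20])), 1)
  expect_false(cl$assignments[1] == cl$assignments[11])

  cl2 <- kmeans_synergies(X, 2, n_init = 20, seed = 3)
  expect_identical(cl$assignments, cl2$assignments)

  expect_equal(kmeans_synergies(X[, 1:4], 4, seed = 1)$inertia, 0, tolerance = 1e-12)
  expect_error(kmeans_synergies(X, 0), "positive")
  expect_error(kmeans_synergies(X, 30), "exceeds")

  # invariance to column order: same partition after permutation
  perm <- sample(ncol(X))
  cl3 <- kmeans_synergies(X[, perm], 2, n_init = 20, seed = 3)
  expect_equal(cl3$assignments == cl3$assignments[1],
               (cl$assignments == cl$assignments[1])[perm])
})

test_that("silhouette-based selection returns the smallest local maximum", {
  set.seed(21)
  # five tight planted groups
  centers <- diag(8)[, 1:5]
  X5 <- do.call(cbind, lapply(1:5, function(j) {
    matrix(centers[, j], 8, 12) + matrix(rnorm(96, 0, 0.04), 8)
  }))
  sel <- select_k(X5, 1:8, n_init = 20, seed = 2)
  expect_equal(sel$chosen_k, 5)

  # two tight clusters: silhouette decreasing beyond 2 -> left endpoint wins
  X2 <- cbind(matrix(c(rep(1, 4), rep(0, 4)), 8, 15) + matrix(rnorm(120, 0, 0.03), 8),
              matrix(c(rep(0, 4), rep(1, 4)), 8, 15) + matrix(rnorm(120, 0, 0.03), 8))
  expect_equal(select_k(X2, 1:8, n_init = 20, seed = 2)$chosen_k, 2)

  # two coarse clusters plus one with fine substructure: silhouette has
  # local maxima at both scales (3 and 5) and the smallest is returned
  set.seed(22)
  e <- function(i) { v <- rep(0, 8); v[i] <- 1; v }
  ctrs <- list(10 * e(1), 10 * e(4), 10 * e(7), 10 * e(7) + e(2),
               10 * e(7) + 2 * e(2))
  X35 <- do.call(cbind, lapply(ctrs, function(ctr) {
    matrix(ctr, 8, 8) + matrix(rnorm(64, 0, 0.005), 8)
  }))
  sel35 <- select_k(X35, 1:8, n_init = 100, seed = 4)
  sil <- sel35$silhouette_by_k
  expect_true(sil["3"] > sil["2"] && sil["3"] > sil["4"])   # 3 is a local max
  expect_true(sil["5"] > sil["4"] && sil["5"] > sil["6"])   # so is 5
  expect_equal(sel35$chosen_k, 3)

  expect_error(select_k(X5[, 1:2], 1:8), "at least 3")
})

test_that("modes are named by dominant muscle with the bilateral-tie rule", {
  # recovery GAS dominant
  c1 <- c(0.1, 1, 0.2, 0.5, 0.1, 0.2, 0.3, 0.1)
  # bilateral TA within 5%
  c2 <- c(1, 0.1, 0.2, 0.3, 0.97, 0.1, 0.2, 0.2)
  cm <- fake_modes(cbind(c1, c2), c(1, 2), cbind(c1, c2), c("A", "A"))
  # activation peaks: mode 1 at 60%, mode 2 at 40% -> order flips
  act <- cbind(dnorm(1:100, 60, 8), dnorm(1:100, 40, 8))
  named <- name_and_order(cm, act)
  expect_equal(named$mode_names, c("W_TA", "W_R_GAS"))
  expect_equal(named$mode_order, c(2L, 1L))
  expect_equal(unname(named$centroids[, "W_R_GAS"]), c1)

  # duplicate names get numeric suffixes
  cm2 <- fake_modes(cbind(c2, c2), c(1, 2), cbind(c2, c2), c("A", "A"))
  named2 <- name_and_order(cm2, act)
  expect_setequal(named2$mode_names, c("W_TA1", "W_TA2"))
})

test_that("cross-stage matching is greedy one-to-one with the r > 0.83 rule", {
  set.seed(23)
  C5 <- matrix(runif(40), 8)
  early <- fake_modes(C5, seq_len(5), C5, paste0("P", 1:5),
                      names = paste0("E", 1:5))
  identical_match <- match_stages(early, early, threshold = 0.83)
  expect_equal(identical_match$pairs$r, rep(1, 5), tolerance = 1e-12)
  expect_true(all(identical_match$pairs$similarity_class == "high"))

  # perturbed centroid: r equals the direct Pearson formula on 8 weights
  C5b <- C5; C5b[1, 1] <- C5b[1, 1] + 0.4
  late <- fake_modes(C5b, seq_len(5), C5b, paste0("P", 1:5),
                     stage = "late", names = paste0("L", 1:5))
  mm <- match_stages(early, late)
  r11 <- mm$pairs$r[mm$pairs$early == "E1"]
  expect_equal(r11, pearson_oracle(C5[, 1], C5b[, 1]), tolerance = 1e-12)

  # 5 early vs 6 late: five pairs, one unmatched late mode
  C6 <- cbind(C5b, runif(8))
  late6 <- fake_modes(C6, seq_len(6), C6, paste0("P", 1:6),
                      stage = "late", names = paste0("L", 1:6))
  mm6 <- match_stages(early, late6)
  expect_equal(nrow(mm6$pairs), 5)
  expect_equal(nrow(mm6$unmatched), 1)
  expect_equal(mm6$unmatched$stage, "late")
})

test_that("paired mode-weight comparison pairs participants and handles ties", {
  set.seed(24)
  W <- matrix(runif(8 * 6), 8)
  parts <- paste0("P", 1:6)
  cm_e <- fake_modes(matrix(rowMeans(W), 8, 1), rep(1, 6), W, parts)
  cm_l <- fake_modes(matrix(rowMeans(W), 8, 1), rep(1, 6), W, parts, stage = "late")
  res <- compare_mode_weights(cm_e, cm_l, 1, 1)
  expect_equal(res$t, rep(0, 8))
  expect_equal(res$p, rep(1, 8))
  expect_equal(res$n_pairs, rep(6L, 8))

  # a participant contributing two synergies has them averaged first
  W2 <- cbind(W, W[, 1] + 0.2)
  cm_e2 <- fake_modes(matrix(rowMeans(W2), 8, 1), rep(1, 7), W2,
                      c(parts, "P1"))
  m <- mode_members(cm_e2, 1)
  expect_equal(nrow(m), 6)
  expect_equal(unlist(m[m$participant == "P1", -1], use.names = FALSE),
               unname((W[, 1] + W2[, 7]) / 2))

  # fewer than 3 shared participants
  cm_s <- fake_modes(matrix(rowMeans(W[, 1:2]), 8, 1), rep(1, 2), W[, 1:2],
                     c("P1", "P2"))
  expect_error(compare_mode_weights(cm_s, cm_l, 1, 1), "fewer than 3")
})
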