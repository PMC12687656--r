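#' Pool unit-max synergy vectors across participants
#'
#' Stacks every participant's synergy vectors for one stage into a single
#' 8 x total matrix with provenance labels, the input to mode clustering.
#'
#' @param fits Named list of `synergy_fit` objects (names = participant ids),
#'   already passed through [unscale_and_normalize()].
#' @return List with `X` (8 x total matrix) and `provenance` (data frame
#'   with `participant`, `synergy`).
#' @export
pool_synergies <- function(fits) {
  if (!length(fits)) stop("no synergy sets to pool")
  if (is.null(names(fits))) names(fits) <- paste0("P", seq_along(fits))
  X <- do.call(cbind, lapply(fits, function(f) f$W))
  prov <- do.call(rbind, lapply(names(fits), function(id) {
    data.frame(participant = id, synergy = seq_len(fits[[id]]$K),
               stringsAsFactors = FALSE)
  }))
  colnames(X) <- paste(prov$participant, prov$synergy, sep = ".")
  list(X = X, provenance = prov)
}

#' K-means clustering of pooled synergy vectors
#'
#' Minimizes the total within-cluster sum of squared Euclidean distances
#' over `n_init` random initializations, keeping the best run. Deterministic
#' given `seed`.
#'
#' @param X 8 x n matrix of pooled unit-max synergy vectors.
#' @param k Number of clusters.
#' @param n_init Random initializations (default 100).
#' @param seed Integer seed.
#' @return List with `assignments` (integer vector), `centroids` (8 x k,
#'   cluster means renormalized to unit maximum), `inertia`.
#' @export
kmeans_synergies <- function(X, k, n_init = 100, seed = 1L) {
  if (k <= 0) stop("k must be positive")
  if (k > ncol(X)) stop("k exceeds the number of pooled synergies")
  if (k == ncol(X)) {
    centroids <- sweep(X, 2, apply(X, 2, max), "/")
    return(list(assignments = seq_len(k), centroids = centroids, inertia = 0))
  }
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(t(X), centers = k, nstart = n_init, iter.max = 200))
  centroids <- t(km$centers)
  centroids <- sweep(centroids, 2, apply(centroids, 2, max), "/")
  rownames(centroids) <- rownames(X)
  list(assignments = unname(km$cluster), centroids = centroids,
       inertia = km$tot.withinss)
}

#' Select the number of synergy modes by mean silhouette
#'
#' Computes the mean silhouette width for each candidate cluster number and
#' returns the smallest k that is a local maximum of the silhouette curve
#' (endpoints compare against their single neighbour). The silhouette is
#' undefined at k = 1 and at k = n, so the effective search runs over
#' 2..min(8, n - 1) even when the requested range starts at 1.
#'
#' @param X 8 x n matrix of pooled synergy vectors.
#' @param k_range Candidate cluster numbers (default 1:8).
#' @param n_init,seed Passed to [kmeans_synergies()] (each k uses a
#'   deterministic sub-seed of `seed`).
#' @return List with `chosen_k` and `silhouette_by_k` (named numeric).
#' @export
select_k <- function(X, k_range = 1:8, n_init = 100, seed = 1L) {
  n <- ncol(X)
  if (n < 3) stop("need at least 3 pooled synergies to select k")
  ks <- sort(unique(pmin(pmax(k_range, 2L), n - 1L)))
  ks <- ks[ks >= 2 & ks <= n - 1]
  if (!length(ks)) stop("no feasible cluster numbers in range")
  D <- stats::dist(t(X))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, max(ks))
  sil <- vapply(ks, function(k) {
    cl <- kmeans_synergies(X, k, n_init = n_init, seed = sub_seeds[k])
    mean(cluster::silhouette(cl$assignments, D)[, "sil_width"])
  }, 1)
  names(sil) <- ks
  is_max <- vapply(seq_along(ks), function(i) {
    left <- if (i > 1) sil[i] > sil[i - 1] else TRUE
    right <- if (i < length(ks)) sil[i] > sil[i + 1] else TRUE
    left && right
  }, TRUE)
  if (!any(is_max)) stop("silhouette curve has no local maximum")
  list(chosen_k = ks[which(is_max)[1]], silhouette_by_k = sil)
}

#' Cluster one stage's pooled synergies into modes
#'
#' Pools, selects the cluster number by silhouette (unless `k` is given),
#' runs k-means, and averages member synergy vectors into unit-max
#' centroids.
#'
#' @param fits Named list of unit-max `synergy_fit` objects for the stage.
#' @param stage Stage label (`"early"`/`"late"`).
#' @param k Fixed cluster count, or `NULL` to select by silhouette.
#' @param cfg A [pipeline_config()].
#' @param seed Integer seed.
#' @return Object of class `clustered_modes`: `centroids` (8 x k),
#'   `assignments`, `provenance`, `pooled`, `silhouette_by_k`, `chosen_k`,
#'   `mode_names` (filled by [name_and_order()]).
#' @export
cluster_stage <- function(fits, stage = "early", k = NULL,
                          cfg = pipeline_config(), seed = cfg$seed) {
  pooled <- pool_synergies(fits)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2)
  sil <- NULL
  if (is.null(k)) {
    sel <- select_k(pooled$X, cfg$cluster_range, n_init = cfg$kmeans_n_init,
                    seed = seeds[1])
    k <- sel$chosen_k
    sil <- sel$silhouette_by_k
  }
  cl <- kmeans_synergies(pooled$X, k, n_init = cfg$kmeans_n_init, seed = seeds[2])
  # centroid = mean of assigned unit-max synergy vectors, renormalized
  centroids <- vapply(seq_len(k), function(j) {
    v <- rowMeans(pooled$X[, cl$assignments == j, drop = FALSE])
    v / max(v)
  }, numeric(8))
  rownames(centroids) <- canonical_channels()
  structure(
    list(stage = stage, centroids = centroids, assignments = cl$assignments,
         provenance = pooled$provenance, pooled = pooled$X,
         silhouette_by_k = sil, chosen_k = k,
         mode_names = paste0("mode", seq_len(k)), mode_order = seq_len(k),
         activation = NULL),
    class = "clustered_modes")
}

#' @export
print.clustered_modes <- function(x, ...) {
  cat(sprintf("<clustered_modes> stage %s: %d modes from %d pooled synergies (%s)\n",
              x$stage, x$chosen_k, ncol(x$pooled),
              paste(x$mode_names, collapse = ", ")))
  invisible(x)
}

#' Name modes by dominant muscle and order them by activation peak time
#'
#' A mode is named `W_<label>` after the centroid's maximal-weight muscle
#' (e.g. `W_R_GAS`). When the same muscle on the two sides ties for
#' dominance within `margin` (5% of the maximum), the side prefix is
#' dropped (`W_TA`). Duplicate names get a numeric suffix (`W_TA1`,
#' `W_TA2`). If per-mode mean activation curves are supplied the modes are
#' reordered by the time of the curve's peak.
#'
#' @param cm A `clustered_modes`.
#' @param activation Optional matrix (100 x k) of per-mode mean
#'   time-normalized activation curves, columns in current mode order.
#' @param margin Relative dominance margin for dropping the side prefix.
#' @return The `clustered_modes` with `mode_names`, `mode_order` (and
#'   reordered centroids/assignments/activation) set.
#' @export
name_and_order <- function(cm, activation = NULL, margin = 0.05) {
  k <- cm$chosen_k
  nm <- character(k)
  for (j in seq_len(k)) {
    w <- cm$centroids[, j]
    top <- which.max(w)
    lbl <- canonical_channels()[top]
    muscle <- sub("^[RS]_", "", lbl)
    other <- paste0(if (startsWith(lbl, "R_")) "S_" else "R_", muscle)
    nm[j] <- if (w[other] >= (1 - margin) * w[top]) paste0("W_", muscle)
             else paste0("W_", lbl)
  }
  if (!is.null(activation)) {
    if (ncol(activation) != k) stop("activation must have one column per mode")
    peak_t <- apply(activation, 2, which.max)
    ord <- order(peak_t)
    cm$centroids <- cm$centroids[, ord, drop = FALSE]
    cm$assignments <- match(cm$assignments, ord)
    nm <- nm[ord]
    activation <- activation[, ord, drop = FALSE]
    cm$mode_order <- ord
  }
  dup <- nm[duplicated(nm)]
  for (d in unique(dup)) {
    idx <- which(nm == d)
    nm[idx] <- paste0(d, seq_along(idx))
  }
  cm$mode_names <- nm
  colnames(cm$centroids) <- nm
  cm$activation <- activation
  cm
}

#' Match synergy modes across training stages
#'
#' Computes the Pearson correlation over the 8 muscle weights for every
#' early x late centroid pair and matches modes one-to-one greedily by
#' descending r. Pairs with r above `threshold` (0.83, the two-tailed
#' critical r at p < 0.01 with 6 degrees of freedom) are classed as highly
#' similar; when mode counts differ the leftovers are reported unmatched.
#'
#' @param early,late `clustered_modes` for the two stages.
#' @param threshold Similarity threshold on r.
#' @return Object of class `mode_match`: data frame `pairs` (`early`,
#'   `late`, `r`, `similarity_class`) and `unmatched` (stage, mode name).
#' @export
match_stages <- function(early, late, threshold = 0.83) {
  ne <- early$chosen_k; nl <- late$chosen_k
  R <- matrix(NA_real_, ne, nl, dimnames = list(early$mode_names, late$mode_names))
  for (i in seq_len(ne)) for (j in seq_len(nl)) {
    R[i, j] <- stats::cor(early$centroids[, i], late$centroids[, j])
  }
  avail_e <- rep(TRUE, ne); avail_l <- rep(TRUE, nl)
  pairs <- list()
  for (s in seq_len(min(ne, nl))) {
    Rm <- R
    Rm[!avail_e, ] <- -Inf; Rm[, !avail_l] <- -Inf
    ij <- arrayInd(which.max(Rm), dim(Rm))
    i <- ij[1]; j <- ij[2]
    pairs[[s]] <- data.frame(
      early = early$mode_names[i], late = late$mode_names[j],
      r = R[i, j],
      similarity_class = if (R[i, j] > threshold) "high" else "below_threshold",
      stringsAsFactors = FALSE)
    avail_e[i] <- FALSE; avail_l[j] <- FALSE
  }
  unmatched <- rbind(
    if (any(avail_e)) data.frame(stage = "early", mode = early$mode_names[avail_e]),
    if (any(avail_l)) data.frame(stage = "late", mode = late$mode_names[avail_l]))
  structure(list(pairs = do.call(rbind, pairs), unmatched = unmatched,
                 r_matrix = R, threshold = threshold),
            class = "mode_match")
}

#' @export
print.mode_match <- function(x, ...) {
  cat(sprintf("<mode_match> %d pairs (threshold r > %.2f)\n", nrow(x$pairs), x$threshold))
  print(x$pairs, row.names = FALSE)
  if (!is.null(x$unmatched) && nrow(x$unmatched)) {
    cat("unmatched:", paste(x$unmatched$stage, x$unmatched$mode, sep = ":", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-participant member weights of one mode
#'
#' Averages a participant's synergy vectors when they contribute more than
#' one synergy to the mode in a stage, preserving one row per participant
#' for paired testing.
#'
#' @param cm A `clustered_modes`.
#' @param mode Mode name or index.
#' @return Data frame: `participant` plus one column per muscle.
#' @export
mode_members <- function(cm, mode) {
  j <- if (is.character(mode)) match(mode, cm$mode_names) else mode
  if (is.na(j) || j < 1 || j > cm$chosen_k) stop("unknown mode: ", mode)
  sel <- cm$assignments == j
  if (!any(sel)) stop("mode has no members")
  W <- cm$pooled[, sel, drop = FALSE]
  who <- cm$provenance$participant[sel]
  agg <- t(vapply(unique(who), function(p) {
    rowMeans(W[, who == p, drop = FALSE])
  }, numeric(8)))
  colnames(agg) <- canonical_channels()
  data.frame(participant = unique(who), agg, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Paired comparison of mode muscle weights across stages
#'
#' For one matched mode, pairs the per-participant member weights of the
#' early and late stages (participants present in only one stage are
#' dropped) and runs a dependent t-test with paired Cohen's d per muscle.
#'
#' @param early_cm,late_cm `clustered_modes` for the two stages.
#' @param early_mode,late_mode Matched mode names.
#' @return Data frame: `muscle`, `n_pairs`, `mean_early`, `mean_late`,
#'   `t`, `df`, `p`, `d`.
#' @export
compare_mode_weights <- function(early_cm, late_cm, early_mode,
                                 late_mode = early_mode) {
  me <- mode_members(early_cm, early_mode)
  ml <- mode_members(late_cm, late_mode)
  common <- intersect(me$participant, ml$participant)
  if (length(common) < 3) {
    stop(sprintf("fewer than 3 paired participants for mode %s (%d)",
                 early_mode, length(common)))
  }
  me <- me[match(common, me$participant), ]
  ml <- ml[match(common, ml$participant), ]
  rows <- lapply(canonical_channels(), function(mu) {
    res <- paired_t(me[[mu]], ml[[mu]])
    data.frame(muscle = mu, n_pairs = length(common),
               mean_early = mean(me[[mu]]), mean_late = mean(ml[[mu]]),
               t = res$statistic, df = res$df, p = res$p,
               d = res$effect_size_d, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
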