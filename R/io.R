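#' EMG trial container
#'
#' @param signal Numeric matrix, 8 rows (channels in canonical order) by
#'   n samples, in consistent amplitude units.
#' @param rate_hz Sampling rate in Hz (600 in the study protocol).
#' @param trial_id Trial identifier.
#' @param stage One of `"early"`, `"late"`, `"other"`.
#' @return Object of class `emg_trial`.
#' @export
emg_trial <- function(signal, rate_hz, trial_id = "trial", stage = "other") {
  signal <- as.matrix(signal)
  if (nrow(signal) != 8L) stop("EMG signal must have 8 rows (channels)")
  if (ncol(signal) < 2L) stop("EMG trial needs at least 2 samples")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("rate_hz must be positive")
  stage <- match.arg(stage, c("early", "late", "other"))
  rownames(signal) <- canonical_channels()
  structure(
    list(signal = signal, rate_hz = rate_hz, trial_id = trial_id,
         stage = stage, channels = muscle_channels()),
    class = "emg_trial"
  )
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf("<emg_trial '%s'> 8 channels x %d samples @ %g Hz (stage: %s)\n",
              x$trial_id, ncol(x$signal), x$rate_hz, x$stage))
  invisible(x)
}

#' Marker trajectory container
#'
#' Positions use the package axis convention: X = anteroposterior (positive
#' anterior, the belt travel direction), Y = mediolateral, Z = vertical.
#'
#' @param positions Numeric array `[n_markers, n_frames, 3]`, metres.
#' @param marker_names Marker names, length `n_markers`.
#' @param rate_hz Frame rate in Hz (120 in the study protocol).
#' @return Object of class `marker_trial`.
#' @export
marker_trial <- function(positions, marker_names, rate_hz) {
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L) {
    stop("positions must be an [n_markers x n_frames x 3] array")
  }
  if (dim(positions)[2] < 2L) stop("marker trial needs at least 2 frames")
  if (dim(positions)[1] != length(marker_names)) {
    stop("marker_names length must match positions")
  }
  dimnames(positions) <- list(marker_names, NULL, c("X", "Y", "Z"))
  structure(
    list(positions = positions, marker_names = marker_names, rate_hz = rate_hz,
         axis_convention = c(X = "AP (positive anterior)", Y = "ML", Z = "vertical")),
    class = "marker_trial"
  )
}

#' @export
print.marker_trial <- function(x, ...) {
  cat(sprintf("<marker_trial> %d markers x %d frames @ %g Hz\n",
              dim(x$positions)[1], dim(x$positions)[2], x$rate_hz))
  invisible(x)
}

#' Extract one marker's trajectory as an [n_frames x 3] matrix
#' @param m A `marker_trial`.
#' @param name Marker name.
#' @export
marker_xyz <- function(m, name) {
  if (!name %in% m$marker_names) stop("marker not present: ", name)
  m$positions[name, , ]
}

#' Load-cell trial container
#'
#' @param force Force trace in newtons (baseline-subtracted, non-negative).
#' @param rate_hz Sampling rate in Hz.
#' @param body_weight_n Participant body weight in newtons.
#' @export
loadcell_trial <- function(force, rate_hz, body_weight_n) {
  if (any(force < 0)) stop("load-cell force must be non-negative after baseline subtraction")
  if (body_weight_n <= 0) stop("body_weight_n must be positive")
  structure(list(force = as.numeric(force), rate_hz = rate_hz,
                 body_weight_n = body_weight_n),
            class = "loadcell_trial")
}

required_markers <- function() {
  c("BELT", "L_HEEL", "R_HEEL", "L_TOE", "R_TOE",
    "L_SHOULDER", "R_SHOULDER", "L_HIP", "R_HIP")
}

# full precision so written files re-read to identical doubles
fmt_num <- function(x) sprintf("%.17g", x)

#' Read an EMG trial from CSV
#'
#' Expects one header row of channel labels (any order; the canonical 8 must
#' all be present) and optionally a leading `time` column in seconds. Columns
#' are reordered into the canonical channel order.
#'
#' @param path CSV file path.
#' @param manifest_entry Optional list with `rate_hz`, `trial_id`, `stage`;
#'   a rate inferred from the time column must agree with the manifest rate
#'   within 0.1%.
#' @param rate_hz Sampling rate used when the file has no time column and no
#'   manifest entry.
#' @return An [emg_trial()].
#' @export
read_emg <- function(path, manifest_entry = NULL, rate_hz = 600) {
  df <- utils::read.csv(path, check.names = FALSE)
  has_time <- "time" %in% names(df)
  assert_full_channel_set(setdiff(names(df), "time"))
  rate <- if (!is.null(manifest_entry$rate_hz)) manifest_entry$rate_hz else rate_hz
  if (has_time) {
    tt <- df$time
    dt <- diff(tt)
    if (any(dt <= 0)) stop("time column must be strictly increasing")
    jitter <- max(abs(dt - mean(dt))) / mean(dt)
    if (jitter > 0.01) stop("non-uniform sampling: time jitter exceeds 1%")
    inferred <- 1 / mean(dt)
    if (!is.null(manifest_entry$rate_hz) &&
        abs(inferred - manifest_entry$rate_hz) / manifest_entry$rate_hz > 0.001) {
      stop(sprintf("sampling rate from time column (%.3f Hz) disagrees with manifest (%g Hz)",
                   inferred, manifest_entry$rate_hz))
    }
    rate <- if (is.null(manifest_entry$rate_hz)) inferred else manifest_entry$rate_hz
  }
  sig <- t(as.matrix(df[canonical_channels()]))
  emg_trial(sig, rate_hz = rate,
            trial_id = manifest_entry$trial_id %||% basename(path),
            stage = manifest_entry$stage %||% "other")
}

#' Write an EMG trial to CSV
#'
#' @param trial An [emg_trial()].
#' @param path Output path.
#' @param time_column Include a `time` column in seconds.
#' @export
write_emg <- function(trial, path, time_column = TRUE) {
  n <- ncol(trial$signal)
  cols <- lapply(seq_len(8), function(i) fmt_num(trial$signal[i, ]))
  names(cols) <- canonical_channels()
  if (time_column) {
    cols <- c(list(time = fmt_num((seq_len(n) - 1) / trial$rate_hz)), cols)
  }
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a marker trial from CSV
#'
#' Columns are `NAME_X`, `NAME_Y`, `NAME_Z` triplets per marker (X = AP,
#' Y = ML, Z = vertical), with an optional `time` column. Gaps (missing
#' values) of at most `max_gap` frames are filled by linear interpolation;
#' longer gaps stay missing and are listed in the `gap_report` attribute.
#'
#' @param path CSV file path.
#' @param rate_hz Frame rate used when the file has no time column.
#' @param max_gap Longest gap (frames) filled by interpolation.
#' @return A [marker_trial()]; `attr(, "gap_report")` lists unfilled gaps.
#' @export
read_markers <- function(path, rate_hz = 120, max_gap = 5) {
  df <- utils::read.csv(path, check.names = FALSE)
  if ("time" %in% names(df)) {
    tt <- df$time
    rate_hz <- 1 / mean(diff(tt))
    df$time <- NULL
  }
  cn <- names(df)
  ok <- grepl("_[XYZ]$", cn)
  if (!all(ok)) stop("non-coordinate column(s) in marker file: ",
                     paste(cn[!ok], collapse = ", "))
  base <- unique(sub("_[XYZ]$", "", cn))
  missing <- setdiff(required_markers(), base)
  if (length(missing)) stop("missing required marker(s): ", paste(missing, collapse = ", "))
  n_frames <- nrow(df)
  pos <- array(NA_real_, c(length(base), n_frames, 3))
  gap_report <- list()
  for (i in seq_along(base)) {
    for (j in 1:3) {
      col <- paste0(base[i], "_", c("X", "Y", "Z")[j])
      if (!col %in% cn) stop("incomplete coordinate triplet for marker ", base[i])
      v <- df[[col]]
      filled <- fill_gaps(v, max_gap)
      pos[i, , j] <- filled$values
      if (length(filled$long_gaps)) {
        gap_report[[length(gap_report) + 1L]] <- data.frame(
          marker = base[i], axis = c("X", "Y", "Z")[j],
          start = vapply(filled$long_gaps, `[`, 1L, 1L),
          length = vapply(filled$long_gaps, `[`, 1L, 2L))
      }
    }
  }
  out <- marker_trial(pos, base, rate_hz)
  attr(out, "gap_report") <- if (length(gap_report)) do.call(rbind, gap_report) else NULL
  out
}

# Linear interpolation of NA runs of length <= max_gap; returns long-gap list
# of c(start_frame, length). Leading/trailing NA runs are never filled.
fill_gaps <- function(v, max_gap) {
  isna <- is.na(v)
  if (!any(isna)) return(list(values = v, long_gaps = list()))
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long_gaps <- list()
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    s <- starts[k]; e <- ends[k]; len <- r$lengths[k]
    interior <- s > 1L && e < length(v)
    if (interior && len <= max_gap) {
      v[s:e] <- v[s - 1L] + (v[e + 1L] - v[s - 1L]) * seq_len(len) / (len + 1L)
    } else {
      long_gaps[[length(long_gaps) + 1L]] <- c(s, len)
    }
  }
  list(values = v, long_gaps = long_gaps)
}

#' Write a marker trial to CSV
#' @param m A [marker_trial()].
#' @param path Output path.
#' @export
write_markers <- function(m, path) {
  n <- dim(m$positions)[2]
  cols <- list(time = fmt_num((seq_len(n) - 1) / m$rate_hz))
  for (i in seq_along(m$marker_names)) {
    for (j in 1:3) {
      cols[[paste0(m$marker_names[i], "_", c("X", "Y", "Z")[j])]] <-
        ifelse(is.na(m$positions[i, , j]), "", fmt_num(m$positions[i, , j]))
    }
  }
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a load-cell trial from CSV
#' @param path CSV with columns `time` (optional) and `force` (newtons).
#' @param body_weight_n Participant body weight, newtons.
#' @param rate_hz Sampling rate used when the file has no time column.
#' @export
read_loadcell <- function(path, body_weight_n, rate_hz = 600) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"force" %in% names(df)) stop("load-cell file needs a 'force' column")
  if ("time" %in% names(df)) rate_hz <- 1 / mean(diff(df$time))
  loadcell_trial(df$force, rate_hz, body_weight_n)
}

#' Write a load-cell trial to CSV
#' @param lc A [loadcell_trial()].
#' @param path Output path.
#' @export
write_loadcell <- function(lc, path) {
  n <- length(lc$force)
  utils::write.csv(
    data.frame(time = fmt_num((seq_len(n) - 1) / lc$rate_hz),
               force = fmt_num(lc$force), check.names = FALSE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
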