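#' Canonical EMG channel set
#'
#' The pipeline records four muscles per leg: tibialis anterior (TA), medial
#' gastrocnemius (GAS), vastus lateralis (VLAT) and biceps femoris long head
#' (BFLH), on the recovery (stepping, prefix `R`) and slipping (stance,
#' prefix `S`) sides. All matrices in the package keep muscles in the fixed
#' canonical order returned by [canonical_channels()].
#'
#' @return Character vector of the 8 canonical channel labels, recovery side
#'   first: `R_TA, R_GAS, R_VLAT, R_BFLH, S_TA, S_GAS, S_VLAT, S_BFLH`.
#' @export
canonical_channels <- function() {
  muscles <- c("TA", "GAS", "VLAT", "BFLH")
  c(paste0("R_", muscles), paste0("S_", muscles))
}

#' @rdname canonical_channels
#' @export
muscle_names <- function() c("TA", "GAS", "VLAT", "BFLH")

#' Build the channel descriptor table
#'
#' @param labels Channel labels; defaults to the canonical 8.
#' @return Data frame with columns `label`, `muscle`, `side`
#'   (`"recovery"`/`"slipping"`).
#' @export
muscle_channels <- function(labels = canonical_channels()) {
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  parts <- strsplit(labels, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed channel label(s): ", paste(labels[bad], collapse = ", "))
  side_code <- vapply(parts, `[[`, "", 1L)
  muscle <- vapply(parts, `[[`, "", 2L)
  if (!all(side_code %in% c("R", "S"))) {
    stop("channel side prefix must be R (recovery) or S (slipping)")
  }
  if (!all(muscle %in% muscle_names())) {
    stop("unknown muscle(s): ", paste(setdiff(muscle, muscle_names()), collapse = ", "))
  }
  data.frame(
    label = labels,
    muscle = muscle,
    side = ifelse(side_code == "R", "recovery", "slipping"),
    stringsAsFactors = FALSE
  )
}

# Check that a label set is exactly the canonical 8 (any order).
assert_full_channel_set <- function(labels) {
  missing <- setdiff(canonical_channels(), labels)
  if (length(missing)) {
    stop("missing EMG channel(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(labels, canonical_channels())
  if (length(extra)) {
    stop("unexpected EMG channel(s): ", paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}
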