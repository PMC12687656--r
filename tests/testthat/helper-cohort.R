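# The reference synthetic cohort (26 participants, fig4-like template,
# 10% envelope noise, no reweighting, null kinematic shifts) and its full
# pipeline analysis, built once and shared by the acceptance checks.
.cohort_cache <- new.env(parent = emptyenv())

flagship_cohort <- function() {
  if (is.null(.cohort_cache$cohort)) {
    .cohort_cache$cohort <- make_cohort(
      n = 26, gt = make_ground_truth(),
      kin_shift = list(initiation_s = 0, step_length_m = 0), seed = 1L)
  }
  .cohort_cache$cohort
}

flagship_report <- function() {
  if (is.null(.cohort_cache$report)) {
    .cohort_cache$report <- analyze_cohort(flagship_cohort(),
                                           pipeline_config(seed = 1L))
  }
  .cohort_cache$report
}
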