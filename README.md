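# slipsynergy

Muscle-synergy analysis of reactive balance responses during stance-slip
perturbation training.

Repeated treadmill-delivered slips train reactive balance: across a
ten-trial block people initiate their recovery step earlier, step longer,
and control their centre of mass better. This package implements the
neuromuscular analysis behind that observation for a standard laboratory
setup (8 surface EMG channels at 600 Hz — TA, GAS, VLAT, BFLH on the
recovery and slipping sides; markers at 120 Hz; a harness load cell), and
asks whether the *muscle synergies* of the recovery response reorganize
between the early (slips 1–2) and late (slips 9–10) training stages.

The core model factorizes the preprocessed activation matrix **M**
(8 muscles × n 10-ms bins) as

    M ≈ W C,   W ≥ 0, C ≥ 0

where the columns of **W** are time-invariant muscle synergy vectors and
the rows of **C** their time-varying recruitment. Fitting uses Lee–Seung
multiplicative updates (20 restarts, best residual kept); the number of
synergies K is the smallest value with global VAF > 90%, every per-muscle
VAF > 75%, and at most a 5-point mean VAF gain from one more synergy.
Synergies are pooled across participants, clustered into modes with
k-means (cluster count = smallest local maximum of the mean silhouette
over 2–8), named by dominant muscle (`W_TA`, `W_R_GAS`, …), matched across
stages by Pearson r with the r > 0.83 similarity rule (the critical r at
p < 0.01 with 6 df), and compared stage-to-stage with paired tests on
muscle weights and on temporal activation features (peak, area, peak time,
25%-of-peak onset). Reactive-step kinematics (step timing and geometry,
COM position/velocity against the base of support, trunk and arm angles,
the strict 30%-body-weight fall rule) are computed from the marker and
load-cell streams.

Because raw trials from such experiments are rarely shareable, the package
ships a seeded synthetic-session generator (`make_cohort()`,
`make_synthetic_session()`) that inverts the analysis model — planted
synergy vectors and Gaussian-bump activations modulating a broadband
carrier, a trapezoidal belt profile, scripted minimum-jerk recovery steps,
segmental-model-consistent markers — so every pipeline stage can be
validated against known ground truth.

## Worked example

```r
library(slipsynergy)

# a 10-participant synthetic cohort with no planted stage effects
cohort <- make_cohort(n = 10, seed = 42,
                      kin_shift = list(initiation_s = 0, step_length_m = 0))
report <- analyze_cohort(cohort, pipeline_config(seed = 7))
print(report)
```

```
== Stance-slip training analysis ==
Participants: 10; falls: 0/100 trials
Synergy dimensionality: early 5-5, late 5-5 (Wilcoxon p = 1.000)
Modes: early 5 (W_TA, W_S_VLAT, W_R_GAS, W_R_VLAT, W_S_GAS); late 5 (W_TA, W_S_VLAT, W_R_GAS, W_R_VLAT, W_S_GAS)
Cross-stage matches:
    early     late         r similarity_class
     W_TA     W_TA 0.9992150             high
 W_S_VLAT W_S_VLAT 0.9988278             high
 W_R_VLAT W_R_VLAT 0.9987425             high
  W_R_GAS  W_R_GAS 0.9976356             high
  W_S_GAS  W_S_GAS 0.9970964             high
Kinematic stage comparison:
          variable mean_early mean_late    t_p       d
 step_initiation_s     0.2412   0.24091 0.9598  0.0164
  step_execution_s     0.1832   0.18502 0.5202 -0.2116
     step_length_m     0.1954   0.19904 0.5070 -0.2185
 ...
```

Reading it: every participant's dimensionality selection recovered the
five planted synergies in both stages; silhouette clustering found five
modes named by their dominant muscles in activation order; with no planted
reweighting all five modes match across stages with r ≈ 0.997–0.999 (all
"high", i.e. above 0.83); and the kinematic stage comparisons are null, as
planted. `write_report(report, "out/")` emits the kinematics, mode,
weight-statistics and feature-statistics tables as CSV plus per-participant
synergies as JSON. Individual stages are available as plain functions
(`emg_envelope()`, `extract_synergies()` — a classed fit with
`summary()`/`coef()`/`plot()` methods — `cluster_stage()`,
`match_stages()`, `trial_kinematics()`, …), and
`inst/cli/slipsynergy.R` wraps simulation and the full run for shell use.

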