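---
title: "Muscle synergy analysis of stance-slip balance training: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle synergy analysis of stance-slip balance training: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slipsynergy)
```

## The scientific problem

Repeated exposure to treadmill-delivered stance slips trains reactive
balance: over a block of ten slip trials, people step earlier, step longer,
and place their centre of mass (COM) more favourably. `slipsynergy`
implements the neuromuscular side of that analysis — whether the *muscle
synergies* underlying the recovery response reorganize between the early
stage of training (slips 1–2) and the late stage (slips 9–10) — together
with the reactive-step kinematics, and a synthetic-cohort generator with
full ground truth so every stage of the pipeline is testable without
access to raw laboratory recordings.

The measurement setup the package models: 8 surface EMG channels (tibialis
anterior, medial gastrocnemius, vastus lateralis, biceps femoris long head,
on the recovery/stepping and slipping sides) at 600 Hz; marker
trajectories at 120 Hz; a harness load cell for fall detection; a
treadmill belt that executes a trapezoidal velocity pulse (0.18 m
displacement, 0.45 m/s peak, 11.35 m/s² acceleration).

## The synergy model

The preprocessed activation matrix $M$ (8 muscles × $n$ 10-ms time bins)
is factorized as

$$ M \approx W C, \qquad W \ge 0,\ C \ge 0, $$

where the columns of $W$ are $K$ time-invariant muscle synergy vectors and
the rows of $C$ their time-varying recruitment coefficients. Fitting
minimizes $\lVert M - WC\rVert_F^2$ with Lee–Seung multiplicative updates
(monotone in the objective; factors floored at $10^{-12}$ so entries are
never absorbed at zero), restarted from 20 uniform-random initializations,
keeping the run with the smallest residual. Reconstruction quality is the
*uncentered* variance accounted for,
$\mathrm{VAF} = 100\,(1 - \lVert M - WC\rVert_F^2 / \lVert M\rVert_F^2)$,
computed globally and per muscle row — the convention of the synergy
literature, which credits reconstruction of raw signal energy rather than
deviations from the mean.

The dimensionality $K$ is the smallest value satisfying all three of:
global VAF > 90%; every per-muscle VAF > 75%; and adding one more synergy
raising the mean per-muscle VAF by at most 5 percentage points (read as
percentage points, consistent with the other two thresholds; at the search
cap the last criterion holds vacuously). If no $K$ up to the cap satisfies
the first two criteria the fit fails loudly, carrying the whole VAF curve
in the error condition.

## Preprocessing

The fixed chain is envelope → window → bin → concatenate → max-normalize →
unit-variance scale:

* **Envelope.** Zero-phase (dual-pass) 2nd-order Butterworth high-pass at
  35 Hz, full-wave rectification, zero-phase dual-pass 2nd-order low-pass
  at 40 Hz. Dual-pass filtering doubles the effective order and cancels
  phase lag, so downstream onset times are unbiased. Zero-phase filtering
  can leave small negative ripples; these are clipped to zero (the
  factorization requires non-negativity) and the clipped mass is recorded
  — on generator output it is well under 1% of total signal mass. All
  zero-phase filtering uses odd-symmetric end padding so filter startup
  transients fall on the reflected pad, not the data.
* **Window.** Belt onset minus 100 ms to recovery-foot touchdown plus
  100 ms, covering the proactive and reactive phases.
* **Binning.** 10-ms bin means; a trailing partial bin is dropped rather
  than padded, avoiding a biased last bin.
* **Concatenation.** The two trials of a stage are joined end-to-end, with
  block boundaries kept for later per-trial time normalization.
* **Max-normalization.** Each muscle is divided by its maximum activation
  across *all ten trials of the session*, whole trials rather than
  analysis windows. Sharing the factors across stages keeps early and late
  amplitudes comparable; using whole trials means muscles whose activity
  peaks outside the perturbation window (the hamstrings peak while
  arresting the trunk after touchdown) scale below 1 inside the window,
  which is what lets a mode's nominally dominant muscle actually dominate
  its centroid.
* **Unit-variance scaling.** Each muscle row is divided by its sample
  standard deviation ($n-1$ denominator) so all muscles weigh equally in
  the factorization; the scales are stored and removed from $W$ after
  extraction, restoring the original scaling, and each synergy is then
  rescaled to unit maximum with the reciprocal folded into its activation
  row (the reconstruction is unchanged to machine precision).

## Clustering, naming and cross-stage matching

Unit-max synergy vectors are pooled across participants within a stage and
clustered with k-means (100 random initializations, best total
within-cluster sum of squares kept). The cluster count is the smallest
local maximum of the mean silhouette; the silhouette is undefined at
$k = 1$ and $k = n$, so the nominal 1–8 search effectively runs over
2–8 (a forced consequence of the definition, with endpoints compared to
their single neighbour). Cluster centroids — the synergy *modes* — are
arithmetic means of member vectors renormalized to unit maximum, named
`W_<dominant muscle>` (side prefix dropped when the same muscle on both
sides is within 5% of the maximum, giving the bilateral `W_TA`), and
ordered by the peak time of the mode's mean activation curve.

Modes are matched across stages by Pearson correlation over the 8 weights,
greedily by descending $r$, one-to-one; with at most 8 well-separated
modes greedy matching coincides with optimal assignment in practice and is
easier to audit. A pair is classed highly similar when $r > 0.83$, the
two-tailed critical value of the correlation coefficient at $p < 0.01$
with $8 - 2 = 6$ degrees of freedom (`critical_r(0.01, 6)` reproduces it).
Within each matched mode, per-muscle weights are compared between stages
by dependent t-test with paired Cohen's $d_z$; a participant contributing
two synergies to one mode has them averaged first, preserving pairing.

Because every member vector is unit-max normalized, a weight change on the
muscle that *is* the column maximum is structurally invisible (the column
simply renormalizes); detectable reweighting lives on the non-dominant
muscles. The package's canonical planted effect is therefore a reduction
of the recovery-side hamstring within the recovery-gastrocnemius mode,
which survives normalization end to end.

## Temporal activation features

Per synergy, each trial's activation segment is linearly interpolated onto
100 points spanning the window, then averaged across the stage's trials.
Features per curve: peak amplitude; peak time (percent of span, first
index on ties for determinism); area under the curve by the trapezoidal
rule on the normalized time axis 0–100 (units: activation × percent-span,
matching the magnitude range of reported response areas); and onset, the
first instant the activation strictly exceeds 25% of its peak. An all-zero
curve has no onset; such values propagate as missing and drop only the
onset comparison's pair.

## Kinematics

Markers are low-pass filtered (zero-phase dual-pass 2nd-order per pass,
effective 4th order) at 6 Hz for all kinematic quantities. Event detection
uses a dedicated gentler 12 Hz filter: detection thresholds a velocity at
0.05 m/s, and at 120 Hz with realistic (≈1 mm) marker noise the
correlated residual noise after a 6 Hz filter both grazes that threshold
often enough to false-trigger a plain "first sustained crossing" rule and
smears step edges by ~3 frames. The detectors therefore anchor on the
velocity peak of the belt pulse (belt onset, BON) or of the heel's step
burst (liftoff and touchdown) and walk outward to the threshold crossing
of the contiguous super-threshold run — same 0.05 m/s threshold, 3-frame
sustain requirement, crossings interpolated between frames. On scripted
synthetic trials this recovers events with mean absolute error below half
a frame and step length within ~1 mm.

Outcome definitions at touchdown (TD): step initiation = BON→liftoff,
execution = liftoff→TD; step length = AP distance from recovery to
slipping heel (positive backward); step width = ML heel distance. AP COM
position is COM minus recovery heel, normalized by base-of-support length
(trailing heel to leading toe, resolved by AP ordering at that frame); ML
COM position is the smaller distance to either toe-defined BOS edge over
BOS width; AP COM velocity subtracts the recovery-heel velocity; ML COM
velocity is absolute (the BOS does not move mediolaterally). Velocities
are central differences on filtered trajectories. Trunk angle is the
sagittal elevation of the hip-to-shoulder midpoint vector (90° upright,
< 90° flexion); arm flexion is the sagittal angle of shoulder→elbow to the
downward vertical, larger arm reported. COM comes from a table-driven
segmental model (13 segments: bilateral thigh, shank, foot, upper arm,
forearm+hand, hemitrunk, head point mass; standard mass fractions halved
across sides) rather than a hard-coded parameterization — any table with
the same columns can be substituted, and the generator uses the default
table so COM recovery is testable to machine precision. A fall is a peak
harness force strictly exceeding 30% of body weight.

## Statistics

Normality by Lilliefors-corrected Kolmogorov–Smirnov (a naive KS with
fitted parameters is anti-conservative); dependent t-tests with paired
Cohen's $d_z = \bar d / s_d$; paired Wilcoxon signed-rank (zero
differences dropped, ties mid-ranked, exact $p$ up to 25 untied pairs);
one-way repeated-measures ANOVA across trials S1, S2, S9, S10 with
$F = MS_{cond}/MS_{cond\times subj}$ and no sphericity correction
(consistent with reporting plain $(c-1),(c-1)(n-1)$ degrees of freedom);
Pearson correlation for mode similarity. No multiple-comparison correction
is applied, mirroring the analysis the pipeline reproduces; the report
tables carry raw $p$ values.

## The synthetic cohort generator

The generator inverts the analysis model so that recovery is a meaningful
test:

* **Synergies.** The `fig4_like` template fixes five modes in
  activation-order: bilateral TA, slipping VLAT, recovery GAS, recovery
  VLAT, slipping GAS dominant, with sub-dominant weights ≤ 0.6. Each
  participant perturbs the template with weight jitter (sd 0.05, clipped,
  re-unit-maxed). Activations are Gaussian bumps at 20–80% of the window
  (width 5% of span, baseline 0.02) — separations of ~3 bump widths, so
  the planted dimensionality is identifiable under the 90/75/5 selection
  rule at the default 10% envelope noise. Earlier, wider bumps (width 8,
  peaks 30–78) made a 3-synergy fit pass all criteria: identifiability of
  the planted structure is a property of the conditions, and these are the
  conditions the generator defines.
* **EMG.** The envelope $E = W C(t)$ (plus truncated-Gaussian envelope
  noise, sd = 10% of the mean window signal) modulates a broadband carrier
  — band-passed 35–250 Hz white noise flattened to near-constant modulus by
  dividing out its own smoothed rectified envelope. Flattening matters: a
  raw Gaussian carrier adds ~20% multiplicative demodulation noise after
  the 40 Hz envelope chain, masking the planted structure; the
  constant-modulus carrier leaves the full filter chain genuinely
  exercised while making $E$ recoverable (per-muscle correlation ≥ 0.99
  at zero envelope noise). Hamstring channels additionally receive a
  post-touchdown stabilization burst (amplitude 0.8, 0.6 s after TD)
  emulating trunk-arresting activity outside the analysis window — the
  physiological reason their whole-trial maxima exceed their in-window
  synergy contribution.
* **Kinematics.** Belt onset uniform in 2–4 s of an 8-s trial; step
  initiation 0.25 s (participant sd 0.06, trial sd 0.015, late-stage shift
  −0.03 s), execution 0.18 s (sd 0.01), step length 0.17 m (participant sd
  0.04, trial sd 0.015, late shift +0.03 m) — means, spreads and
  adaptation directions of the young-adult cohorts this protocol reports.
  The recovery foot executes a minimum-jerk backward step with a small
  vertical clearance arc; the upper body carries a smooth backward COM
  excursion; markers get 1 mm Gaussian noise. Load-cell traces peak at 10%
  body weight — no synthetic participant falls, matching the observed 0%
  fall rate.
* **Seeding.** All randomness derives from one root seed via deterministic
  sub-seeds; cohorts are byte-reproducible.

What the generator does *not* emulate: motor-unit-level EMG structure,
electromechanical delay, crosstalk between channels, marker occlusion
patterns beyond simple gaps, inter-muscle correlation of envelope noise,
or participants whose true dimensionality differs from the template.
Passing recovery tests therefore demonstrates that the pipeline's
inference chain is correct and calibrated under the stated generative
model — not that real recordings satisfy that model.

## Problem sizes and runtime choices

The reference validation cohort is 26 participants × 10 trials with the
full signal chain; dimensionality selection, clustering and matching run
on it end to end. Type-I-error calibration and power of the planted
effects (hamstring reweighting Δ = −0.2, sd 0.1; initiation −0.03 s; step
length +0.03 m) are evaluated over 100 script-level cohorts — the
generator's ground-truth weights and scripts — rather than 100 full signal
cohorts; the signal-level recovery error that separates the two layers is
itself measured (sub-frame events, ~1 mm step length, synergy cosine
≈ 0.97) on the full-chain cohort, so the script-level loops are a faithful
proxy at a fraction of the cost. Statistical size checks use 2000 null
simulations at the study's n = 26.

## Known limitations

* Greedy mode matching can in principle differ from optimal one-to-one
  assignment when modes are poorly separated; with ≤ 8 high-contrast modes
  it has not been observed to.
* Silhouette selection inherits k-means' sensitivity to initialization;
  100 restarts per k makes this negligible at pooled-cohort sizes.
* The per-column unit-max convention makes dominant-muscle reweighting
  unobservable by construction (see above); conclusions about "no change
  in the dominant muscle" are therefore not informative.
* Event detection assumes one step burst per trial; multi-step recoveries
  would need the detector generalized.
* The KS normality variant is Lilliefors; results are reported but not
  used to switch tests automatically.
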