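---
title: "Motor-cognitive dual-task screening from wearable inertial sensors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-cognitive dual-task screening from wearable inertial sensors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdtscreen)
```

## The screening problem

Mild cognitive impairment (MCI) often expresses itself in motor control
before it is obvious in conversation: movement draws on the same
cognitive resources that a concurrent task competes for. A
motor-cognitive dual-task (MCDT) protocol exploits this as a
"brain-stress test": a subject performs a simple motor task — 15 s of
self-paced fore-finger tapping (FTAP), 15 s of toe tapping with the heel
pinned (TTHP), or a 10-m straight walk (GAIT) — alone (single task, CL0)
and while counting backwards by 1, 3 or 7 (dual task, CL1–CL3). Motor
performance is measured by a wearable inertial unit (tri-axial
accelerometer in g, tri-axial gyroscope in deg/s, 100 Hz) on the finger
or foot dorsum; the decline of each motor parameter under load — the
dual-task cost — carries the diagnostic signal.

`mcdtscreen` implements this pipeline end to end: a synthetic cohort
generator with ground-truth labels, signal conditioning, tap-cycle and
stride segmentation, kinematic feature extraction, dual-task cost,
nonparametric group statistics and MMSE correlation, and age-adjusted
logistic screening models evaluated by ROC. Because no raw recordings
from the original clinical cohorts are publicly deposited, the
simulator is a first-class module: every downstream stage is validated
against the generator's truth labels rather than against irreproducible
clinical values.

## The signal model

The generator uses the simplest waveforms for which every extracted
feature is well defined.

**Tapping.** A recording is 3 s of static hold (baseline pose
acquisition) followed by 15 s of tap cycles. Each cycle of period $T_k$
is a biphasic angular-velocity shape on the flexion axis: a positive
raised-cosine opening lobe whose time integral equals the cycle's
excursion angle $E_k$ (so the peak opening velocity is
$w_o = 2E_k/d$ for lobe duration $d$), a matching negative closing
lobe, then rest. Period and excursion vary cycle to cycle
($T_k \sim N(T, \sigma_T)$, $E_k \sim N(E, \sigma_E)$, truncated).
The accelerometer reads gravity rotated through the integrated flexion
angle plus a tangential lever-arm term and white noise; the vertical
axis reads 1 g in the rest pose.

**Gait.** Sagittal foot angular velocity as a per-stride template:
near-zero flat-foot stance (62% of the stride) followed by one dominant
raised-cosine swing peak. The walk covers
$\lceil \mathrm{distance} / \mathrm{stride\ length} \rceil$ strides
between standing lead-in/lead-out transients.

**Counting.** Correct-answer counts are Poisson draws whose means are
the per-group, per-task, per-load presets. Poisson was chosen because
it is mean-exact, integer and non-negative, and the reported group SDs
for counting scores are close to $\sqrt{\text{mean}}$ anyway.

## Cohort presets

Two groups are simulated: cognitively normal adults (CNA) and MCI.
Demographics come from truncated normals parameterised by group medians
and interquartile ranges (sd = IQR/1.349): age centred at 65 vs 73
years, MMSE at 29 vs 27 (floor 24 — lower scores are excluded by the
eligibility rule), with group-specific sex, education and frailty
category frequencies. Frailty follows the standard five-criterion
phenotype: 0 criteria = not frail, 1–2 = pre-frail, ≥3 = frail.

Motor presets encode three effects, all multiplicative on the CL0
baseline per load: slowing (period/stride-duration multipliers rising
to 1.25 CNA / 1.38 MCI at CL3), amplitude reduction (0.88 / 0.80) and
cycle-to-cycle variability inflation (1.40 / 1.70). CNA stride length
declines 2.24 m → 2.04 m across loads, MCI 1.92 m → 1.81 m. Tap-rate
presets put CNA near 29 and MCI near 20 taps per 15 s at CL2.

Critically, every subject draws their own motor profile from
between-subject distributions (a mean-one lognormal rate factor for
tapping, CV 0.35–0.55; normal factors for stride length/duration;
per-subject cycle-variability levels). Published group feature tables
for such cohorts show between-subject SDs comparable to the group mean
differences (e.g. tap counts of 29 ± 17 vs 20 ± 16), and without this
spread a simulated cohort separates perfectly at every load, which is
not the phenomenon under study. The presets were fixed once from those
magnitudes and directions; they are conditions, not tuning knobs.

**What the generator does not emulate:** multi-segment limb
biomechanics, sensor orientation drift, magnetometer channels, turning
or non-straight gait, missing-at-random sensor dropouts, and any direct
mechanistic coupling between an individual's MMSE and their motor
parameters (the pooled MMSE–motor correlation arises from the group
contrast alone). Passing tests therefore show that the pipeline's
machinery is correct and well calibrated at study scale — not that it
would reach any particular accuracy on real clinical recordings.

## Signal conditioning and segmentation

All six channels are filtered with a fourth-order low-pass digital
Butterworth filter, 5 Hz cut-off, applied zero-phase
(forward–backward) so segment boundaries are not lag-shifted; a causal
single-pass mode is retained for parity experiments. Endpoints are
handled by odd-reflection padding of up to 200 samples: the pole radius
of this filter at 100 Hz is ≈ 0.85, so a ~2 s pad lets the
zero-initial-state startup transient decay below 1e-12 before the data
begin, which is what makes the DC-preservation contract (constant in,
same constant out to 1e-9) hold at the edges.

Tapping recordings then lose their first 3 s: the gyroscope bias is the
per-channel mean over that static window (subtracted everywhere), and
the mean accelerometer vector over the window is stored as the baseline
pose for later gravity removal.

A **tap cycle** is one positive (opening) lobe of the movement-axis
angular velocity followed by its paired negative (closing) lobe. Lobes
are located as excursions beyond 10% of the recording's peak absolute
velocity — a relative threshold, so the rule is unit- and
subject-robust — and expanded to their bounding zero crossings (which
also merges threshold chatter caused by noise). A trailing opening lobe
with no closing partner is discarded as an incomplete cycle.

A **stride** is anchored on the mid-swing angular-velocity peak — a
single robust landmark — rather than on heel-strike/toe-off zero
crossings. Peaks must exceed 50 deg/s and be 0.5 s apart; boundaries
fall midway between consecutive peaks, and the first and last detected
strides are dropped by default to exclude gait initiation and
termination. Detection therefore needs at least three strides.

## Features

Eleven tapping features per recording: tap count; excursion
(trapezoidal integral of the opening lobe, deg), peak opening and peak
closing velocity (deg/s), each aggregated as per-cycle mean and SD;
signal magnitude area $\mathrm{SMA} = \frac{1}{T}\sum
(|a_x|+|a_y|+|a_z|)\,\Delta t$ of the gravity-removed acceleration (an
energy-expenditure proxy); jerk RMS (first difference of the
acceleration magnitude over $\Delta t$); and skewness and kurtosis of
the acceleration magnitude. Kurtosis uses the Pearson (non-excess)
convention — published values for these tasks straddle 3, the Gaussian
value under that convention. Peak (not mean) per-cycle velocities are
the standard tapping kinematics.

Sixteen gait parameters: total time (first to last retained stride),
velocity (distance/total time), stride count, stride duration
mean/SD, stride length mean/SD, swing and stance time mean/SD,
cadence, swing-peak velocity mean/SD, a symmetry index (odd- vs
even-stride mean duration ratio) and a normalized jerk smoothness
score. A single dorsum-mounted IMU cannot measure stride length
directly, so length uses the uniform-allocation convention
`distance / n_detected_strides`, with an SD from duration-proportional
allocation; the convention is recorded in the output schema. The
swing/stance split places the swing window at the 10%-of-peak
threshold crossings around the mid-swing peak.

That is 38 features per cognitive load (11 + 11 + 16). Missing
features (e.g. cycle aggregates of an empty segment list) propagate as
missing, never as zeros.

## Dual-task cost

For each feature and dual-task load, the cost is the percent change
from the single-task value. Two denominator conventions circulate: the
default divides by the single-task (CL0) value,

$$\mathrm{DTC} = \frac{P_{DT} - P_{ST}}{P_{ST}} \times 100,$$

which matches the dominant dual-task-literature convention; dividing by
$P_{DT}$ instead is available as `dt_denominator`, and the two satisfy
$\mathrm{DTC}_{dt} = \mathrm{DTC}_{st}/(1 + \mathrm{DTC}_{st}/100)$
cell-wise. Which convention a given published analysis used is often
ambiguous, so every output table records its mode in metadata.
Denominators below 1e-9 in feature units yield missing values, never
infinities. The assembled table has 38 × 4 base + 38 × 3 DTC = 266
motor columns, plus correct-answer counts (3 tasks × CL1–CL3) that are
screened alongside but not counted among the 266.

## Statistics

Group differences use the two-sided Wilcoxon rank-sum (Mann–Whitney)
test: exact when the pooled n ≤ 20 without ties, otherwise the normal
approximation with tie-corrected variance. Categorical demographics use
the uncorrected Pearson chi-square (no Yates correction — this is the
variant that reproduces the standard worked examples for 2 × 2 and
2 × 3 demographic tables). MMSE association uses Spearman's rho with a
t-approximation p (exact permutation enumeration available for n ≤ 8),
with no covariate adjustment. No multiple-testing correction is applied
anywhere at screening — the full per-feature result table is returned
so a user can apply one. Screening keeps features with unadjusted
p < α (α = 0.05); a selection rule that kept *non*-significant
features would leave the downstream models nothing to work with, so
the threshold is read in the conventional direction.

## Models and evaluation

One logistic regression per task × dual-task load, on the features
selected at that cell plus age (always included as a covariate), with
predictors standardized before fitting. With ~10 predictors and 44
subjects, complete separation is near-certain; when detected, the model
is refit with a small ridge penalty (1e-4 on the standardized scale,
configurable) so coefficients stay finite, and the condition is
flagged. The ridge refit is an in-package Newton/IRLS routine because
the cell can legitimately contain a single predictor.

ROC curves sweep all distinct score thresholds (ties collapse onto one
threshold); AUC is the trapezoidal integral, which equals the
tie-adjusted concordant-pair probability. The operating point maximizes
Youden's J, with ties broken toward higher specificity — screening
models in this setting are typically specificity-favoring. Cells with
no selected feature are skipped and reported with the reason, mirroring
protocols in which a task fails to differentiate groups at the lightest
load.

Evaluation is in-sample by default: at n = 44 that is the only
evaluation a small clinical pilot can print, and it is optimistic.
A stratified k-fold mode (`evaluation = "cv"`) gives the honest
counterpart; the analysis scripts report both side by side, and every
ROC result is labelled with its evaluation mode.

## Numerical choices and degenerate inputs

* Zero-phase padding: odd reflection, `min(n - 1, 200)` samples (see
  above for why 3 × the filter order would not meet the DC contract).
* Segment indices are 1-based inclusive in R; JSON serialization uses
  the 0-based half-open convention.
* Tap lobes shorter than 2 samples, recordings shorter than the
  baseline window, walks with fewer than 3 detected strides, empty
  groups, single-class labels and constant correlation inputs all fail
  loudly with specific errors; flat movement channels yield empty
  segment lists with warnings.
* Constant classifier scores produce a degenerate two-point ROC with
  AUC 0.5 and a NaN-threshold operating point, flagged.
* All randomness flows from one integer seed through a
  multiplicative-congruential child-seed scheme, so cohorts and signals
  are bit-reproducible and every recording is independently seeded.

## Problem sizes used by the test suite

The suite validates at the scales the analysis itself uses: the full
27 + 17 synthetic study for the end-to-end checks; 200 subjects per
group (metadata only) for demographic-distribution checks; 100 seeded
replicates for the noisy tap-count and screening-power Monte-Carlos;
n = 5000 for the closed-form two-Gaussian AUC recovery
($\mathrm{AUC} = \Phi(d/\sqrt 2)$); n = 2000 for logistic coefficient
recovery; and 10,000 null replicates for the rank-sum type-I-error
calibration.

## Known limitations

The exact published definitions of the 11 tapping and 16 gait features
live in companion engineering papers and supplementary material that
are not publicly machine-readable; the feature set here covers every
symbol those analyses report on, but individual definitions (notably
normalized jerk and the symmetry index) are reconstructions, and the
column schema is designed so a renamed or redefined feature does not
change any code. Clinical AUC values from the original 44-subject
cohort are not reproducible targets, because those recordings were
never deposited; the package's claims are about the pipeline, the
algebra and the recovery of known synthetic truth.
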