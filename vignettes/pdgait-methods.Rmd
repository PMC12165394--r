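---
title: "From kinematic trajectories to motor-cognitive statistics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From kinematic trajectories to motor-cognitive statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdgait)
```

# Overview

pdgait implements a complete analysis path for clinical gait studies in
Parkinson disease: it segments the Timed Up and Go (TUG) test into seven
timed phases from the whole-body center-of-mass (COM) trajectory, extracts a
panel of spatiotemporal and kinematic walking metrics from heel/toe markers
and joint rotation matrices, and relates those motor outcomes to cognitive
scores (response inhibition, working memory, mental rotation) through a
normality-gated correlation battery, per-metric multivariable ordinary least
squares (OLS), and a multivariate analysis of variance (MANOVA) with the
four classical test statistics. Because studies of this kind rarely deposit
participant-level recordings, the package ships first-class synthetic
generators whose ground truth is analytic, so every stage of the pipeline is
testable end to end.

# TUG phase segmentation

The TUG test (stand from a chair, walk 3 m, turn, walk back, sit) is
partitioned by eight event markers detected on the filtered COM x
(direction of travel) and z (height) coordinates:

| event | rule |
|---|---|
| stand initiation | z first exceeds the seated baseline (plus a noise tolerance) |
| stand end | first prominent local maximum of z |
| gait-initiation end | forward excursion exceeds 1 m |
| turn begin / end | forward excursion exceeds / falls below 3 m |
| walk-2 end | forward excursion falls below 1 m |
| sit begin | z falls below 95% of standing height |
| sit end | forward excursion returns to the start |

The "starting" COM position is the mean over an opening 0.5 s seated window
(configurable); the trial must actually begin seated, which the detector
verifies by requiring no sustained (≥ 50 ms) height excursion inside that
window — isolated noisy samples are tolerated. Standing height is the
filtered z value at the detected stand-end peak.

Seven phase durations telescope between consecutive events: sit-to-stand,
gait initiation, walk 1, turn, walk 2, slow down & turn, sit down. The
mapping is the only ordering-consistent assignment of eight markers to seven
contiguous phases, so the durations always sum to the time from stand
initiation to sit end.

Numerical choices:

* All threshold crossings are located with linear sub-frame interpolation
  between the bracketing frames. Event times retain that sub-frame
  precision (a `frame` column gives the nearest 120 Hz frame). Rounding both
  ends of a phase to whole frames would consume a full frame of error
  budget by quantization alone, which is why durations are computed from
  the interpolated times.
* The stand-end peak requires a prominence of at least the z-noise
  tolerance (default 5 mm) so measurement noise cannot spawn spurious
  peaks.
* The stand-initiation threshold is baseline + tolerance rather than a
  strict inequality, making the rule robust to mm-scale noise. The sitting
  threshold, by contrast, is an absolute fraction (95%) of standing height
  — that is the published rule — so it is deliberately *not* invariant to
  adding a constant to z, while all baseline-relative events are.
* If the sit-end rule (x back at its start) never fires — participants can
  end seated slightly forward of where they started — the detector falls
  back to the time of minimum forward excursion after sit begin and flags
  the event.

# Smoothing

Kinematic series are smoothed with a zero-phase low-pass filter before event
detection: a 4th-order Butterworth at 12 Hz applied forward and backward
(`filtfilt`), with reflective padding long enough for the start-up transient
of the zero-state IIR to decay below numerical noise before the data begin.
In gait analysis a generalized cross-validated quintic spline (GCVSPL) is a
common smoother; with the cutoff pinned at a fixed 12 Hz the cross-validation
criterion is inert, and the zero-phase Butterworth is the reproducible
equivalent. A GCV smoothing-spline alternative remains selectable through
`filter_spec(method = "spline")`. Passband amplitude (below cutoff/3) is
preserved within 1%, and the forward-backward application guarantees no
phase lag, verified by peak-time preservation. Short interior NaN gaps (up
to 0.1 s) are bridged by linear interpolation before filtering; longer gaps
are an error.

# Walking metrics

Gait events use the coordinate-based rule family: foot strike at local
maxima of heel-x relative to the COM (foot maximally ahead), foot off at
local minima of toe-x relative to the COM (foot maximally behind), per side,
with a 1 cm prominence guard and a 0.6 s minimum separation. The per-side
event series is trimmed to the span between first and last strike and must
alternate strike/off.

* **Velocity** — length of a central 3.3 m capture zone divided by the
  sub-frame interpolated COM crossing times. The zone is centered on the
  midpoint of the COM excursion by default (a proxy for the calibrated
  volume midpoint, which a laboratory can supply explicitly). Whether the
  published analyses used zone length or COM displacement over the interval
  is ambiguous; both modes are implemented and agree for a monotone
  crossing, zone length being the default.
* **Stride length** — anterior heel displacement between consecutive
  same-side strikes, averaged over both sides.
* **Double support** — per stride, the sum of the two double-limb intervals
  (each foot strike to the opposite foot's off), averaged across strides of
  both sides; strides truncated at trial boundaries are skipped. The
  per-interval decomposition is also exposed.
* **Minimum toe clearance** — per swing, the minimum toe height above the
  floor reference within the middle 80% of the swing (trimming avoids
  boundary artifacts at foot off/strike), averaged per side. The floor
  reference defaults to the per-side *median stance-phase toe height*: the
  stance phase is when the toe actually sits on the floor, and a median
  over those frames is unbiased under measurement noise, whereas the
  trial-minimum of a noisy series is biased low by roughly three noise
  standard deviations (≈ 6 mm at σ = 2 mm), which would systematically
  inflate clearance estimates beyond their recovery tolerance. Trial-minimum
  and fixed-height references remain available for floor-calibrated labs.
* **Joint ROM** — rotation matrices are decomposed with the XYZ Cardan
  sequence (`Rx(α)·Ry(β)·Rz(γ)`), the first angle being flexion-extension;
  angles are continuity-unwrapped and gimbal proximity (|β| > 89°) is
  flagged. ROM is max − min of the flexion-extension angle per gait cycle
  (strike to same-side strike), averaged across cycles. Only the first
  Cardan angle feeds the reported metrics; the other planes are returned
  but unreported.
* **Shoulder symmetry angle** — the bilateral pair (L, R) maps to
  `(45° − atan2(L, R)) / 90° × 100`, 0% for perfect symmetry, ±50% when one
  side vanishes. The signed value is retained internally; the reported
  metric is the magnitude, matching the non-negative convention of clinical
  tables.
* **Impaired-side rule** — toe clearance and hip ROM enter the analysis
  from the clinically impaired side only; bilateral or no impairment
  contributes the average of sides. The side assignment is consumed as
  trial metadata; the package does not infer it.

Repeated trials of a condition are averaged element-wise; a metric missing
in one trial falls back to the other trials' values with a log message.

# Statistical battery

Every analysis variable (3 cognitive scores, 7 TUG phases, 6 single-task
and 6 dual-task walking metrics) is first checked with the Shapiro-Wilk
test (Royston approximation, as implemented in `stats::shapiro.test`). The
correlation method is gated per pair: Pearson only if *both* members passed
normality, Spearman otherwise. The published description ("Pearson or
Spearman depending on the normality test") does not state an either/both
rule; the either-member-fails-to-Spearman gate is the conservative choice
and the one consistent with rank-based results being reported for skewed
scores.

The battery computes 3 × 19 = 57 pairwise correlations. P-values use the
t-approximation (df = n − 2) for both methods; exact Spearman p-values are
not attempted. Confidence intervals use the Fisher z transform with
SE = 1/√(n−3) for Pearson and the Fieller-corrected SE = √(1.06/(n−3)) for
Spearman. Published tables of this kind rarely state their CI variant, so no
attempt is made to reverse-engineer one; the method used is documented in
the output. No multiplicity correction is applied by default, matching
standard practice for exploratory clinical batteries of this size; the raw
p-values allow any correction downstream. Missing data are handled
pairwise-complete for correlations and listwise for OLS/MANOVA.

Each dependent variable is then fit by OLS on the three cognitive scores
(plus intercept), reporting B, SE, t, p (df = n − 4), 95% CI, R² and
adjusted R². Collinearity is screened with VIFs from auxiliary regressions
(`1/(1 − R²_j)`).

The MANOVA fits the multivariate linear model per response block (TUG
phases; single-task metrics; dual-task metrics). For each coefficient the
hypothesis SSCP is formed from the estimate and its contrast covariance, and
the eigenvalues λ of `E⁻¹H` yield Wilks' Λ = ∏1/(1+λᵢ), Pillai's trace
= Σλᵢ/(1+λᵢ), the Hotelling-Lawley trace = Σλᵢ and Roy's greatest root
= max λᵢ. F approximations follow Rao (Wilks), the standard Pillai form,
and the Pillai-Samson form (Hotelling-Lawley); Roy is reported with its
upper-bound F and flagged as a bound. For a one-degree-of-freedom term all
four statistics reduce to the same exact F, and with a single response the
omnibus term's Wilks Λ equals 1 − R² of the OLS fit — both identities are
enforced in the test suite at 1e-8/1e-10, and the implementation is
cross-checked against an independent MANOVA implementation (`car::Manova`).
MANOVA output follows the conventional (statistic, F, num df, den df, p)
column layout.

# Synthetic data

The generators exist to make every pipeline stage testable without recorded
data; their waveforms are chosen for closed-form event times and extrema,
not biomechanical realism.

**TUG trajectories.** COM height rises from the seated value along a cubic
smoothstep, peaks with a Gaussian overshoot bump (3 cm, width 0.08 s) at
stand end — the curve is smooth there with an exactly-known maximum — then
descends along a half-cosine whose crossing of the sitting threshold lands
at the programmed sit-begin time. Forward progression accelerates with a
half-cosine speed ramp timed so the 1 m and 3 m crossings occur exactly at
the programmed phase boundaries; the cruise speed between them is therefore
fixed at 2 m divided by the walk-1 duration, and a nominal walk-speed
parameter that disagrees with it by more than 25% is a parameter error. The
turn is a sinusoidal excursion above 3 m with slope-continuous entry and
exit; the return leg mirrors the outbound one; and the final slow-down
decays toward a sustained creep speed chosen in closed form so the
start-line crossing happens exactly at the programmed sit-end time with a
well-conditioned (non-vanishing) approach speed — an asymptotic approach
would make that crossing arbitrarily sensitive to noise, which is a
property of the waveform, not of the detector. Ground-truth event times are
the exact crossing times of the detection rules on the continuous
noise-free waveforms; where no algebraic form exists (the two
height-threshold crossings) they are located by root-finding at 1e-12 s on
the closed-form curves. Defaults reproduce typical early-stage disease
phase durations (1.13, 0.59, 1.73, 2.98, 1.89, 1.32, 1.33 s) and COM
heights (0.55 m seated, 0.93 m standing).

**Walking trials.** The COM advances at constant speed v; heel and toe
markers oscillate sinusoidally about it at stride frequency f = v/SL, with
the toe phase lag set to −πf·DS so the programmed double-support time DS is
realized exactly (the implied stance fraction, T/2 + DS/2, sits near the
physiological 60%). Swing-phase toe height follows
TC·sin²(πs) + 3TC·sin²(2πs) over swing fraction s — a two-hump curve whose
unique interior minimum is exactly TC at mid-swing, safely inside the
trimmed window. Hip and shoulder flexion-extension are sinusoids with the
programmed ROMs, embedded in proper rotation matrices with small fixed
out-of-plane angles. The walkway is 15 m, so the central 3.3 m capture zone
has more than 5 m of lead-in. Strike/off times, stride length, double
support, toe clearance and ROMs are all emitted in closed form. Defaults
mirror typical single-task walking in this population (v = 1.32 m/s,
SL = 1.36 m, DS = 0.34 s, TC = 0.034 m, hip ROM 50.4°).

**Cohorts.** A Gaussian copula draws participant rows with a target
correlation matrix and transforms each margin to its declared shape,
moment-matched to the stated mean and SD. The default marginals reproduce
the typical cohort table (n = 19) of this literature; the five variables
whose observed distributions are right-skewed (response inhibition, TUG
sit-down time, both shoulder asymmetries, dual-task double support) default
to lognormal margins, which reliably trip the Shapiro-Wilk gate at n = 19.
The default correlation targets embed the published cognitive-by-TUG and
cognitive-by-dual-task coefficients and leave everything else at zero.
Jointly those targets are strongly non-positive-semi-definite (three
mutually uncorrelated predictors cannot each correlate at 0.5–0.7 with the
same responses), so the generator applies a nearest-PSD repair
(`Matrix::nearPD`) before sampling, logs it, and returns both the target
and the repaired matrix; the repair shrinks the strongest entries
substantially (e.g. 0.65 → ≈ 0.44), which is a property of the printed
table, not of the sampler. Studies of specific dependence structures should
therefore pass a bespoke (already-PSD) target matrix, as the recovery
checks do.

Noise is additive i.i.d. Gaussian on positions only; rotation matrices stay
exactly on SO(3). Every generator is bitwise deterministic given a seed.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: stride-time and stride-length variability,
asymmetric or festinating gait, turning strategies and freezing episodes,
soft-tissue and pose-estimation artifacts that are neither white nor
Gaussian, and any coupling between cognitive load and waveform shape. The
synthetic cohort encodes linear (copula) dependence only.

# Verification scale and tolerances

The test suite and the acceptance script rerun the pipeline at sizes chosen
to make the checks statistically meaningful while staying lightweight:
100–200 randomized TUG trials (noise-free recovery within one frame at
120 Hz; with 2 mm noise, within 25 ms in ≥ 95% of trials), 50–100 walking
trials at 2 mm noise (median recovery error ≤ 2% per metric, ≤ 2 mm for toe
clearance), 10⁵ random rotations for the Cardan round trip (< 1e-9°), 500–
1000 null cohorts for the type-I rate of the battery (within [3.5%, 6.5%]
at α = 0.05), and n = 5000 cohorts for correlation recovery (±0.03).
Identities (Wilks vs R², one-df F equivalence, normal equations, unit VIF)
are checked at 1e-8–1e-12.

# Known limitations

* COM is consumed as an input channel; the package does not compute it from
  a segmental anthropometric model.
* C3D ingestion is not provided; the supported trajectory format is the
  documented CSV dialect (wide, one row per frame, `# key: value` header).
* The impaired-side assignment is metadata supplied by the user.
* Spearman p-values use the t-approximation, which is mildly conservative
  below n ≈ 10.
* Roy's greatest root is reported with an upper-bound F, as is standard;
  its p-value is anti-conservative and flagged accordingly.
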