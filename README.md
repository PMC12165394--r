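# pdgait

Motor-cognitive gait analysis for Parkinson disease kinematics.

In early-stage Parkinson disease, subtle gait changes track specific
cognitive domains — working memory and visuospatial processing more than
response inhibition — and those relationships sharpen under dual-task load.
Quantifying them requires a pipeline from raw 3D kinematics to a
statistical battery: segmenting the Timed Up and Go (TUG) test into timed
phases, extracting spatiotemporal and kinematic walking metrics, and
relating both to cognitive scores. pdgait implements that pipeline for
gait researchers and clinician-scientists working with marker-based or
markerless motion-capture exports.

## What it computes

**TUG phase segmentation.** Eight event markers detected on the filtered
center-of-mass (COM) trajectory — stand initiation (z above its seated
baseline), stand end (first prominent z peak), 1 m / 3 m forward-excursion
crossings out and back, the 95%-of-standing-height sitting threshold, and
return to the start — partition the trial into seven phases: sit-to-stand,
gait initiation, walk 1, turn, walk 2, slow down & turn, sit down.

**Walking metrics.** Foot strikes and foot offs from the extrema of heel/toe
position relative to the COM; capture-zone velocity; stride length; double
support (both double-limb intervals per stride); minimum toe clearance in
the trimmed swing; hip and shoulder flexion-extension ROM from the XYZ
Cardan decomposition `Rx(α)·Ry(β)·Rz(γ)` of joint rotation matrices; and
the bilateral symmetry angle `(45° − atan2(L, R))/90° × 100` for shoulder
ROM. Side-specific metrics follow the impaired-side rule.

**Statistical battery.** Shapiro-Wilk normality per variable; 57 pairwise
correlations (3 cognitive × 19 gait variables), Pearson when both margins
are normal and Spearman otherwise, with Fisher-z 95% CIs; multivariable OLS
per gait metric on the three cognitive scores (B, SE, t, p, CI, R², adj-R²);
MANOVA per response block with Wilks' Λ, Pillai's trace, Hotelling-Lawley
trace and Roy's greatest root (Λ = ∏ 1/(1+λᵢ) etc. from the eigenvalues of
E⁻¹H); and a VIF collinearity screen.

**Synthetic generators.** TUG trajectories, walking trials and participant
cohorts with analytic ground truth (exact event times, metric values and
correlation structure), so the full pipeline is testable without recorded
data.

## Worked example

```r
library(pdgait)

# a TUG trial with 2 mm marker noise, segmented into phases
sim    <- simulate_tug_trajectory(seed = 42, noise_sd = 0.002)
phases <- compute_phase_times(detect_tug_events(sim$trial))
phases
#> # A tibble: 7 × 2
#>   phase           duration
#>   <fct>              <dbl>
#> 1 sit_to_stand       1.06
#> 2 gait_initiation    0.587
#> 3 walk1              1.73
#> 4 turn               2.98
#> 5 walk2              1.89
#> 6 slow_down_turn     1.31
#> 7 sit_down           1.34
```

Durations are seconds; this simulated patient stood up in 1.06 s and took
2.98 s to turn, typical of mild motor impairment. The walking panel:

```r
walk  <- simulate_walking_trial(seed = 42, noise_sd = 0.002)
panel <- summarize_walking_trial(walk$trial)
dplyr::select(panel, velocity, stride_length, double_support,
              toe_clearance, hip_rom, shoulder_symmetry)
#> # A tibble: 1 × 6
#>   velocity stride_length double_support toe_clearance hip_rom shoulder_symmetry
#>      <dbl>         <dbl>          <dbl>         <dbl>   <dbl>             <dbl>
#> 1     1.32          1.36          0.337        0.0337    50.4           0.00212
```

1.32 m/s with a 1.36 m stride and 34 mm of minimum toe clearance — the
programmed simulator truth (1.32, 1.36, 0.34, 0.034, 50.38) recovered
within tolerance from noisy data. The statistical battery on a synthetic
19-participant cohort:

```r
cohort <- simulate_cohort(n = 19, seed = 42)$cohort
report <- run_full_battery(cohort)
report
#> <stat_report> n = 19 participants
#>   normality: 22 variables (4 non-normal)
#>   correlations: 57 pairs (10 significant at alpha = 0.05)
#>   OLS fits: 19 dependents; MANOVA blocks: 3; max VIF: 1.24

dplyr::slice_min(tidy(report, "correlations"), p, n = 3)
#>   predictor           dependent   method       r       p ci_lower ci_upper
#> 1 response_inhibition velocity_dt spearman 0.653 0.00245    0.269    0.858
#> 2 response_inhibition hip_rom_dt  spearman 0.635 0.00348    0.241    0.850
#> 3 working_memory      velocity_dt pearson  0.621 0.00457    0.232    0.839
```

Four skewed variables fail the Shapiro-Wilk gate, so their pairs run
Spearman; the strongest associations link cognition to dual-task velocity
and hip ROM, the pattern the cohort generator embeds. `tidy()` / `glance()`
expose every table as a tibble, `write_report()` emits deterministic
TSV/JSON, and `autoplot()` / `plot_correlation_heatmap()` draw the standard
figures.

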