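---
title: "Grading LV diastolic function from CMR velocity data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading LV diastolic function from CMR velocity data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrdiastole)
```

## The problem

Left-ventricular diastolic dysfunction (DD) — impaired relaxation and
rising filling pressure — is routinely graded from transthoracic
echocardiography (TTE) using the 2016 ASE/EACVI criteria. The same
physiological quantities are measurable by cardiovascular MR: transmitral
inflow velocities from in-plane phase-contrast imaging (the E and A waves
and the E-wave deceleration time, DT), early-diastolic mitral annular
velocities (e′) from tracked insertion points on 4-chamber cines, and
indexed left-atrial volume (LAVi) from biplane area–length geometry. This
package implements that measurement pipeline, the grading decision tree
with configurable cutoff sets, the calibration of CMR-analog cutoffs from
paired data, and the statistics used to quantify agreement between the two
modalities. A synthetic-data generator with analytic ground truth makes
every stage testable without patient data.

## Measurement models

### Transmitral E, A and DT

`roi_peak_series()` reduces a stack of 2D velocity frames to a waveform by
taking, per frame, the peak velocity inside a circular ROI (default radius
20 mm) placed at the valve level; the inflow sign is auto-detected from
the dominant diastolic direction and the series reported positive toward
the apex. `detect_E_A()` finds E as the highest diastolic peak in the
early window and A as the last distinct peak before the cycle ends.
Peaks are discrete local maxima without sub-frame interpolation — frame
peaks are what both modalities report clinically — above a noise floor
estimated from successive differences (`max(0.15·v_max, 4·σ̂)`). Where no
end-systolic time is supplied, diastole is taken to start at the global
minimum of the early-cycle flow, E is searched in the first 60% of
diastole and A in the remainder; both fractions are arguments. A fused or
absent A wave is reported as missing with a qc flag rather than guessed.

`deceleration_time()` implements the clinical extrapolation rule: a
straight line is fitted to the initial descending limb of the E wave and
DT is the time from the peak to that line's zero crossing,
`DT = v_fit(t_E)/|slope|`. The guideline does not define "initial
descent", so the fit window holds the descending samples between 90% and
50% of the peak, extending toward 30% when fewer than three samples fall
there (and falling back to the first five positive descending samples on
very coarse grids). On a noise-free triangular wave the result equals the
constructed descent duration to machine precision, which the tests
assert. A descent truncated by the A onset is fitted on the available
samples and flagged.

### Annular e′

`project_displacement()` projects each tracked insertion point onto the
long axis — the unit vector from the apex reference to the valve midpoint
at frame 0, held fixed over the cycle for stability on noisy tracks — and
zeroes it at end-diastole. `e_prime()` differentiates by central
differences (a 5-point quadratic Savitzky–Golay smoother is available but
off by default; the reference analysis used raw tracks) and takes the peak
basal-directed velocity between the time of maximal systolic excursion and
75% of the remaining cycle, which excludes the atrial wave. Velocities
are reported as positive magnitudes, matching TTE convention, and
`e_average` is exactly the arithmetic wall mean. Because a central
difference is a window average, coarser frame spacing can only lower the
recovered peak on smooth tracks — the tests assert this monotonicity,
which mirrors the clinically observed sensitivity of e′ to temporal
resolution.

### Atrial volumetry

`la_volume()` is the biplane area–length formula
`V = 0.85·A_2ch·A_4ch / L` (cm², cm → mL exactly). Whether `L` should be
the LA length at maximal volume or the longer of the two view lengths is
genuinely ambiguous in practice; the function takes the caller's value
and records the convention in the result rather than guessing. BSA
defaults to Mosteller (the most common convention in CMR reporting), with
DuBois selectable; the two differ by under 5% over ordinary adult
anthropometry, which a grid test verifies.

## The grading decision tree

`dd_grade()` implements the 2016 logic with the cutoffs abstracted into a
`dd_thresholds` set, each criterion carrying its own comparator. Two sets
ship: `"TTE-2016"` (guideline cutoffs, strict where the guideline prints
them strict) and `"CMR-paper"` (ROC-calibrated CMR analogs: e′ septal ≤ 4,
e′ lateral ≤ 9, E ≤ 57 cm/s, E/e′ ≥ 12, E/A ≥ 1.5 and ≤ 0.9, LAVi ≥ 34
mL/m²). The TR-velocity cutoff (> 280 cm/s) follows the guideline
convention since the analog tables leave it unstated; TR is a TTE
measurement in either pathway.

Two boundary decisions were genuinely open and are resolved as follows:

* **E/A partition boundaries are inclusive in both sets** (grade 1 at
  E/A ≤ low cutoff with E low; grade 3 at E/A ≥ high cutoff). The grading
  branch partitions the ratio axis into three regions; inclusive extreme
  regions keep the partition exhaustive, and the worked grade-3 example
  (E = 80, A = 40, hence E/A exactly 2.0) is only classifiable this way.
* **Ratios are compared at 1-decimal reporting precision.** E/A and E/e′
  cutoffs are stated at one decimal, and clinical readers compare reported
  (rounded) ratios against them. `dd_grade()` therefore rounds the raw
  ratio to one decimal before comparison; velocities and LAVi are compared
  raw. This is what makes a measured E/A of 55/37 = 1.486 equivalent to
  its reported value 1.5 at the ≥ 1.5 boundary.

The screening branch (preserved EF, no known myocardial disease) counts
the four criteria {e′ low in either wall, E/e′ high, TR high, LAVi high}
over those available: more than half positive proceeds to grading, exactly
half is indeterminate, fewer is normal. `assume_myocardial_disease = TRUE`
enters the grading branch directly. Missing TR or LAVi narrows the count
with a qc flag; every comparison made is recorded in the
`criteria_fired` audit trail. `presence()` collapses grades to the
presence/absence super-category with indeterminate counted as present.

## Cutoff calibration

`calibrate_cutoff()` scans all midpoints between sorted unique values
(plus open extremes), choosing the cutoff maximizing Youden's J with ties
broken toward the more specific threshold, and reports the trapezoidal
AUC. The choice of Youden's J is a design decision — the criterion behind
the published analog cutoffs is unstated — and the frozen `"CMR-paper"`
set remains available regardless of recalibration. A test fixes the
implementation against an exhaustive brute-force oracle and against an
independent ROC library. `linear_analog_cutoff()` provides the companion
regression-based analog: the OLS-fitted CMR value at the TTE cutoff.

## Agreement statistics

All standard steps call base R: exact binomial CIs via `binom.test()`
(Clopper–Pearson reproduces the published intervals, e.g. a lower bound of
63% for 23/28 and for 8/8, where Wilson intervals would not), Pearson via
`cor.test()`, OLS via `lm()`, logistic fits via `glm()`. Cohen's kappa is
unweighted, per the source analyses. ICC(2,1) — two-way random effects,
absolute agreement, single measure — is computed from the Shrout–Fleiss
mean squares directly and cross-checked in tests against an independent
`aov()`-based computation.

The multivariable pipeline screens candidates at univariable p < 0.5 and
then eliminates backward until all retained predictors hold p ≤ 0.05.
Likelihood-ratio tests are used at both stages: the interesting
small-cohort case is complete separation (the published three-predictor
model classifies its cohort perfectly), and Wald statistics collapse there
while LRT statistics do not. Separation is detected and flagged, with
coefficients reported under a warning as a direction rather than a finite
optimum. `loo_accuracy()` refits the entire selection pipeline inside
each fold — the stricter reading of leave-one-out, with no information
leakage — and reproduces the characteristic optimism gap between
in-sample and cross-validated accuracy at n ≈ 28. The frozen published
model is available as `predict_dd_reference_model()`; its printed
coefficients put p = 0.5 exactly on the stated plane and saturate at the
group means.

## The synthetic-data generator

The generator exists so that every extraction stage has analytic ground
truth; its defaults are fixed at the study conditions and are not tuned.

* **Waveforms** (`simulate_waveform()`): 36 ms frame spacing over a
  1000 ms RR interval (retrospectively gated acquisition), an E pulse with
  sinusoidal rise and strictly linear descent so DT is exact by
  construction, a raised-cosine A pulse, peak times snapped to frame
  mid-points so noise-free sampled maxima equal the configured peaks, and
  i.i.d. Gaussian frame noise (drift available, off by default). Pulses
  leaving fewer than three descent samples are rejected.
* **Annulus tracks** (`simulate_annulus_track()`): raised-cosine systolic
  descent, an early-diastolic velocity trapezoid whose plateau equals the
  configured e′ (the plateau, 110 ms against a 36 ms frame spacing,
  guarantees one central-difference sample sees the exact plateau rate),
  and an atrial return closing the displacement loop.
* **Paired cohorts** (`simulate_paired_cohort()`): a latent panel per
  subject from normal-function or dysfunction-range distributions (group
  means/SDs at the reported cohort values; dysfunction fraction 9/31),
  measured additively — TTE = truth + noise, CMR = truth + bias + noise —
  so the configured bias and ±1.96·SD difference spread are recovered in
  the limit; a convergence test checks both within 5% at n = 10⁴.
  Modality noise SDs derive from the reported difference spreads
  (spread/(1.96·√2)); septal and lateral e′ share correlated latent values
  (ρ = 0.6) and correlated within-modality noise (ρ = 0.5), which brings
  the e′-average difference spread to its reported magnitude. Physiologic
  floors apply to the latent truth only (they essentially never bind);
  measured values stay exactly additive, and ratio denominators are
  guarded against non-positive draws.

What the generator does **not** emulate: image-domain physics (k-space,
VENC aliasing, phase wraps), beat-to-beat variability, any hemodynamic
coupling between parameters (E, e′ and LAVi are drawn independently given
the group), or the skewness of real LAVi distributions. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated noise model, not clinical accuracy on real images.

## Numerical choices and degenerate inputs

Empty ROIs, all-NaN frames, undersampled tracks (frame spacing ≥ RR/4),
degenerate long axes, non-decaying E descents, single-class calibration
labels, zero-variance regressors and empty contingency margins all error
or flag explicitly rather than returning silent numbers. Seeded
generators use a private RNG stream and restore the caller's state.
Comparisons of grades use the fixed level order normal, indeterminate,
grade 1–3; cross-tabulations are 5×5 in that order with TTE on rows.

## Problem sizes

The test suite and the acceptance script use 100 seeded waveforms for
recovery statistics, n = 10⁴ cohorts for moment-convergence and
limits-of-agreement coverage, n = 3000 for cutoff calibration, 200
simulated scan–rescan studies of n = 10, and a study-sized n = 31 cohort
for the logistic pipeline — sizes chosen so stochastic checks are stable
at the stated tolerances.

## Known limitations and documented discrepancies

* The 5×5 grade-level kappa computed from the published contingency table
  is 0.51; the source text reports 0.49. The package reports its computed
  value — the hand computation from the printed marginals is
  reproducible — and makes no attempt to match the printed one.
* The published figure caption's E/e′ values are not exactly E divided by
  the printed e′ (80/9 ≠ 10; 55/8 ≠ 8.2), suggesting a single-wall vs.
  average inconsistency in the caption. `dd_grade()` always computes E/e′
  from the e′ average when components are present.
* A simulated scan–rescan study at the reported variance components
  (between-subject SD 13, within-subject SD 13.2/(1.96·√2)) has a
  variance-component ICC of 0.88; the reported value for that measurement
  is 0.92, consistent with sampling variability at n = 10 but not
  derivable from the printed spreads alone.
* e′ by CMR is biased low against TTE at coarser temporal resolution; the
  package treats this as a property to reproduce (the generator's bias
  defaults and the resolution-monotonicity test), not an error to correct.
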