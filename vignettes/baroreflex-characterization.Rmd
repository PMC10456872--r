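---
title: "Characterizing baroreflex-mediated cardiorespiratory interactions"
author: "barogeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing baroreflex-mediated cardiorespiratory interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barogeo)
```

## The problem

The baroreflex couples three physiological systems: a change in arterial
blood pressure elicits compensatory adjustments of the heart period and,
more subtly, of the respiratory rhythm.  In cardiomyopathy this feedback
is degraded in ways that differ between ischemic and dilated etiologies.
`barogeo` quantifies the coupling from noninvasive recordings by asking a
conditional question: *when the vascular state is rising, falling, or
stable on the beat scale, how do the cardiac and respiratory increments
behave?*

Four event series are the substrate:

* **BBI** — beat-to-beat interval (ms), from ECG R peaks;
* **SBP / DBP** — per-beat systolic and diastolic pressure (mmHg), as the
  per-heartbeat extrema of the continuous pressure wave;
* **TT** — respiratory cycle duration (s), between successive breath
  onsets.

## The procedure

**Signal processing.** Raw channels are linearly detrended; samples at or
beyond three standard deviations are treated as artifacts and bridged by
linear interpolation so the sampling grid is preserved (removal would
desynchronize the channels).  R peaks come from a Pan-Tompkins-style
detector (5–15 Hz band-pass, squared derivative, 150 ms integration,
adaptive threshold with a 250 ms refractory period); the detector's own
timing is refined on the band-passed signal to sub-sample accuracy.
Breath onsets are negative-to-positive zero crossings of the flow signal
low-passed at 1 Hz, refined against the unfiltered flow.  All four event
series are linearly interpolated onto one common 1 Hz grid — spanning the
latest first event to the earliest last event — and decimated to 0.25 Hz
after a zero-phase 8th-order FIR low-pass at 0.1 Hz, so that cardiac-band
power cannot alias into the respiratory-scale analysis.  Plain
subsampling is deliberately not used.

**Delta sub-spaces.** Beat-scale variability is the first difference
`dX[n] = X[n+1] - X[n]`.  Each delta series is z-scored per subject, which
keeps subjects exchangeable and thresholds comparable; the pooled
alternative is available through the `pooled_thresholds` argument of
`baro_characterize()`.  For a vascular driver (dSBP or dDBP) the
no-change band is

```
Th = alpha * (max(dXv) - min(dXv)) / 2,    alpha = 0.15 by default,
```

and samples are labelled `up` (`dXv > Th`), `nc` (`-Th <= dXv <= Th`,
boundary inclusive) or `down` (`dXv < -Th`).

**Geometric characterization.**  Within each sub-space the paired
`(dBBI, dTT)` increments form a scatterplot.  Its shape is summarized by
a containment polygon: the 95% of points nearest the cloud centroid are
kept and their convex hull is taken.  This rule is deterministic and
rotation invariant; the containment definition is otherwise open, and a
nearest-to-centroid rule reproduces the intended visual of a convex
outline excluding extremes.  Area and centroid come from the shoelace
sums; the polygon is decomposed into a fan of triangles from the
centroid to consecutive vertex pairs, yielding per-triangle areas,
occupancy counts, the angle `beta` at the centroid and `theta`, the mean
of the two base angles.  (Two readings of "the vertex angle" are
possible — the mean of both base angles, or the angle at the leading
vertex only; the former is the default, the latter a one-line change.
The fan guarantees `sum(beta) = 360°` and `sum(Ar) = A`, which the test
suite enforces.)

**The 168 indices.**  For each driver (SBP, DBP) and each sub-space
(`u`, `nc`, `d`): eight statistics of dBBI (mean, SD, kurtosis, skewness,
IQR, CV, sub-space occupancy probability, mean absolute deviation),
the same eight for dTT, and ten joint morphology indices (area,
area/points, area/vertices, vertex count, mean centroid distance,
`theta`, `beta`, `theta - beta`, mean triangle occupancy, mean triangle
area): 26 × 6 = 156.  The remaining 12 are the six descriptive statistics
of dSBP and dDBP computed globally, *before* z-scoring — after
normalization their mean and SD are the constants 0 and 1, so the
physical-unit series is the informative choice (mmHg per grid step).
Kurtosis is non-excess (normal = 3), skewness is the Fisher moment
coefficient, quantiles use linear interpolation, and CV is `sd/m × 100`
(flagged missing when the mean is exactly zero).  Note that the
occupancy index is by construction identical between the dBBI and dTT
blocks of one (driver, sub-space); the duplicated name is retained so
the fixed 168-entry inventory round-trips.  Empty sub-spaces yield
missing values, never imputations.

**Screening and classification.**  Indices are compared between groups
with a two-sided Mann-Whitney test — exact enumeration when the pooled
sample is at most 12 without ties, otherwise the tie- and
continuity-corrected normal approximation.  Significant indices
(p ≤ 0.05) are paired; pairs with |Spearman rho| ≥ 0.7 are discarded as
collinear (0.7 is the conventional cut; configurable).  Each pair feeds
soft-margin SVMs over three kernels on standardized features,

```
gaussian:  K = exp(-||x-y||^2 / (2 sigma^2))
laplace:   K = exp(-||x-y|| / sigma)
anova:     K = (sum_k exp(-sigma (x_k-y_k)^2))^d
```

with an exhaustive grid over C ∈ {0.5, 1, 2.2, 5, 10},
sigma ∈ {0.5, 0.8, 1, 1.5, 2, 3} and d ∈ {1, 2, 3} (ANOVA only) — ranges
chosen to bracket the optima typically reported for standardized
two-feature problems.  Every candidate is scored by leave-one-out
cross-validation; fold standardization statistics come from the training
subjects only.  The dual problems are solved by a compact SMO
(maximal-violating-pair) solver implemented in C++, which keeps the full
grid × LOOCV search fast; the test suite cross-checks its decision
values against an independent SVM implementation (`kernlab`).

Ties in LOOCV accuracy break by higher sensitivity, then fewer support
vectors, then lexicographic pair name, making the search deterministic.

**Screening bias.**  Screening on the full sample and then
cross-validating is optimistically biased.  The default mode therefore
re-screens inside every training fold; folds in which a candidate pair
fails in-fold screening fall back to a majority-class prediction, since
a feature that would not have been selected cannot honestly drive a
prediction.  (Full nested cross-validation is out of scope by design.)
`full_sample_screen = TRUE` restores the single full-sample screen, the
protocol commonly used with full-sample feature selection, for
comparability.  A label-permutation test in the suite
verifies that the honest mode keeps searched accuracy near chance on
shuffled labels.

**Positive class.**  Sensitivity and specificity depend on which group
is "positive".  This is explicit (`positive =` argument, and per
comparison in the pipeline configuration) rather than positional: in
patient-vs-control comparisons the patient group is conventionally the
sensitivity class, and in etiology comparisons the class of interest
(e.g. the dilated group) must be declared.

## The synthetic generator

Clinical recordings of this kind are restricted, so the package carries
a generator whose *ground truth is known*: one slow latent vascular
fluctuation (unit-SD AR(1), 15 s correlation time — a Mayer-wave-scale
process) drives per-beat SBP/DBP (set points 120/70 mmHg, 4 mmHg slow
SD, 0.5 mmHg beat noise), the heart period (mean 900 ms, 25 ms SD, with
a baroreflex coupling of 0.45 and a respiratory sinus-arrhythmia share
of 0.3), and the breath duration (mean 3.6 s, SD 0.3 s, vascular
coupling 0.1).  All couplings are first-order linear — the simplest
mechanism that produces sub-space-dependent contrasts; no further
physiological realism is claimed.  Raw signals, when requested, are
synthesized from the event-level truth: template R waves at beat times,
triangular pressure pulses whose window extrema equal the injected
SBP/DBP exactly, and a phase-continuous flow oscillation whose
negative-to-positive crossings are the breath onsets.

Group effects are expressed in *index-SD units*: `effect_tt = 1` raises
the respiratory-vascular coupling of the non-reference groups by 0.24,
which shifts the `SBP-dTTm-d` index (mean respiratory increment while
systolic pressure falls) by one within-group SD; `effect_bbi = 1` lowers
the baroreflex coupling by 0.175, shifting `SBP-dBBIsd-nc` by one SD in
the opposite direction (weaker coupling leaves relatively more
heart-period variance in the no-change band).  The two constants were
fixed once by a calibration simulation (400 subjects per arm, 15-minute
records, realized d = 0.99 at one effect-SD) and verified to scale
linearly up to two SD (realized d = 2.00); they are not runtime
parameters.  With both effects zero the groups are exchangeable
by construction, which is what the null-calibration check exploits.

What the generator does *not* emulate: arrhythmic beats and ectopy,
waveform-morphology pathology, non-stationary drifts, measurement
dropouts, and between-subject parameter heterogeneity (within a group
all subjects share parameters, so index variance is purely sampling
variance).  Passing tests therefore demonstrate that the pipeline
recovers known couplings from clean coupled signals — not that it is
robust to every artifact of clinical data.

## Numerical choices and degenerate inputs

* Resampled BBI/TT values are clipped away from zero so filter ringing
  on pathological inputs cannot violate positivity.
* The decimation filter is applied after demeaning with reflection
  padding; zero-state transients would otherwise dominate the deltas at
  the record edges.
* Polygon fits need at least 4 points and a non-collinear cloud;
  otherwise a degenerate model (area 0) is returned and the morphology
  block is missing.  Occupancy assignment uses sign tests with a scaled
  tolerance; boundary points go to the lowest-index triangle, and any
  numerical straggler joins the triangle it violates least, preserving
  the occupancy-sum invariant exactly.
* Values exactly at ±Th are no-change, as the band is defined with
  closed inequalities.
* A constant delta series (zero variance) is an error, not a silent
  degenerate z-score; the zero-noise generator configuration exercises
  this on purpose.
* Outlier bridging can in principle flag at most 1/9 of samples (a
  Chebyshev bound at three SDs), so the >20% warning is defensive only.
* All randomness flows from explicit seeds; cohort subject seeds are
  derived deterministically from the base seed, and identical
  configurations reproduce byte-identical feature tables.

## Problem sizes used in the checks

The acceptance checks run cohorts of 20 + 20 subjects with 15-minute
records (≈ 220 samples on the 0.25 Hz grid): 20 replicate cohorts for
the 1-SD recovery rate, 20 null cohorts for the false-positive rate,
and 10 cohorts with 2-SD effects for the end-to-end LOOCV search.  These
sizes give the recovery tests useful power while keeping a full run in
the minutes range; the search space is additionally bounded by `top_k`
(default 10 indices by screening p-value) before pairing.

## A worked example

```{r example, eval = FALSE}
library(barogeo)

cfg <- sim_config(c(CON = 20, CMP = 20), effect_tt = 2, effect_bbi = 2,
                  seed = 77)
cohort <- simulate_cohort(cfg)
features <- characterize_cohort(cohort)

model <- model_search(features[, feature_schema()], features$group,
                      positive = "CMP")
print(model)
#> <baro_model CMP vs CON>
#>   pair:   SBP-dBBIm-u + SBP-dTTm-d
#>   kernel: gaussian (C = 10, sigma = 2)
#>   LOOCV:  Acc 100.0% | Sn 100.0% | Sp 100.0%
#>   counts: TP 20, FN 0, TN 20, FP 0
```

## Known limitations

* The containment rule is one deterministic reading of "a polygon
  containing 95% of the values"; alpha-shape or probabilistic-contour
  alternatives would give different absolute areas (comparisons between
  groups are less sensitive to the choice).
* `theta` uses the mean-of-base-angles reading; the angle-at-single-
  vertex alternative is a one-line change in `triangle_morphology()`.
* WFDB and EDF readers are not provided; raw input is CSV
  (`time_s, ecg, bp, rf`) or tidy event-series CSV.
* Honest-mode model search still selects hyperparameters by LOOCV
  accuracy on the same folds; its accuracies are comparative scores, not
  unbiased generalization estimates.
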