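---
title: "Methods: pattern similarity and decoding across overlapping environments"
author: "overlapMPS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pattern similarity and decoding across overlapping environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes, the
assumptions behind each stage, and the design choices made where the
problem left them open.  It states no empirical result that the test suite
and `scripts/acceptance.R` do not themselves compute.

## The design encoded by `CityEnvironment`

Three virtual cities share one circular layout: six peripheral stores on a
circle plus a shared center store.  City 1 holds stores {1..6}; City 2
replaces store 4 with store 7 on the same slot; City 3 further replaces
stores 2 and 6 with 8 and 9.  The resulting overlaps are 5 (cities 1–2),
4 (2–3) and 3 (1–3) stores, with stores 1, 3, 5 common to all three.
Stores therefore partition into sharing classes — unique {4, 8, 9},
two-shared {2, 6, 7}, three-shared {1, 3, 5} — and a *triad* of stores
(one retrieval question) inherits the class of the set of cities
containing all three of its members.  Travel durations from the center are
8 s for stores 3, 5, 6, 9 and 16 s for the rest, so temporal triads
(center on top, two peripheral stores below) have interval indices
16/24/32 s, and each city's six stores split 3/3 by duration, making
9 of the 15 bottom-store pairs unequal — exactly the design's 60:40
unequal:equal quota.

**Coordinates.** The source design shows but does not tabulate store
positions; the package adopts a regular hexagon of configurable radius
(default 1) with the center at the origin.  All geometry flows from this
choice: `enumerateSpatialTriads()` brute-forces every triad's distance
index, and on the default layout there are 5 distinct values
(2, 1+√3, 3, 2√3, 2+√3).  Richer, irregular layouts produce more distinct
distances; because the distance bins are always derived by enumeration, no
distance count is hard-coded anywhere.  Spatial triads draw on the six
peripheral stores only; the center store appears only atop temporal
triads.

**Schedules.** Retrieval is 12 runs × 15 trials (180 trials): one block of
six spatial and one of six temporal runs, two runs per city per task, with
city order pseudorandomized so no city repeats back-to-back and every city
appears once before any repeats (enforced across the block boundary too).
Each temporal run presents all 15 bottom-store pairs once; spatial runs
sample 6 equal + 9 unequal triads from the city's triad space, forcing
each sharing class present so every between-city condition is populated.
Trials run 18.13 s: a 9 s probe, a 7.77 s active baseline, and a 1.36 s
fixation gap placed last.  The localizer is 2 runs × 18 trials; each of
the six studied stores {2, 4, 6, 7, 8, 9} appears three times per run,
once per triad position, 2–12 trials between repetitions (seeded rejection
sampling), flanked by unstudied filler stores.  Equality of the two
summand distances is labeled with a 1e−9 tolerance; distance indices are
rounded to 9 decimals throughout so geometrically equal distances are
exact ties.

## The synthetic generator

`makeStoreCodes()` samples latent neuron-level codes (default 200 neurons)
and `simulateTrialPatterns()` composes, per trial,

> presented-store codes + η · (unpresented unique-store codes of the
> city) + γ · city code + β · D · schema direction + κ · interval code +
> λ · slot codes, → voxels via a nonnegative mixing matrix, + Gaussian
> noise scaled by 1/tSNR per voxel,

with every strength an `effectSpec()` parameter defaulting to zero, so the
default generator is a calibrated null.  Choices worth knowing:

- **Exact shared-store correlations.**  A store shared by *m* cities gets
  *m* vectors whose empirical pairwise correlation equals `rho_shared`
  *exactly* (an orthonormal mean-zero basis rotated by the Cholesky factor
  of the target Gram matrix), removing Monte-Carlo slack from recovery
  tests.  Feasibility requires `rho_shared > −1/(m−1)`; for the
  three-shared stores that is −0.5.  `rho_shared` may be a pair of values
  (two-shared, three-shared) to study per-level differentiation.
- **The center store contributes no signal.**  It is identical in every
  environment and present in every temporal trial, so a center code would
  be a constant shared by all temporal trials; because the pair conditions
  differ in their spatial/temporal composition, that constant would bias
  between-city contrasts through task composition rather than any memory
  mechanism.  The measured effect of including it is a spurious positive
  shift of the three-shared-minus-unique null; with it excluded both the
  spatial-only and pooled nulls are centered at zero.
- **Neuron-to-voxel mixing.**  Voxels pool all neurons with gamma weights
  (columns unit-normalized).  This is the bridge used to check that
  separation (ρ ≈ 0) and repulsion (ρ < 0) planted at the neuron level
  keep their sign at the voxel level.  A consequence worth understanding:
  with ρ imposed at the neuron level, each realization's voxel-level
  correlation is a nonzero random constant (≈ ±1/√n_neurons), i.e. each
  simulated subject has a small *true* idiosyncratic effect.  Within-
  subject pair-level tests correctly detect it, so "type-I" calibration is
  only meaningful across realizations — the acceptance suite tests the
  null by group-level inference over cohorts of simulated subjects, and
  assesses per-subject power with a disjoint-pair test (no trial reused)
  that limits pair dependence.
- **tSNR heterogeneity.**  Per-voxel tSNR is lognormal (meanlog log 40,
  sdlog 0.3 — a plausible 3T gray-matter spread) and noise SD scales as
  median(tSNR)/tSNR, which is what makes the eight-level tSNR filter
  consequential.
- **Sizes.**  200 neurons → 100 voxels per region, 180 retrieval + 36
  localizer trials per subject: one simulated subject takes well under a
  second, so recovery sweeps use 20–50 subjects and calibration sweeps
  100–1000, sizes chosen to make each estimator's sampling error small
  relative to the bands being checked.
- **Correctness and censoring** default to 90% correct and 5% censored at
  the schedule level; the BOLD path derives censoring from its simulated
  framewise-displacement trace instead (spike probability per frame,
  threshold 0.5 mm).

What the generator does **not** emulate: physiological noise and scanner
drift structure (noise is AR(1) in the BOLD path, white at the pattern
level), spatial autocorrelation between voxels, behavioral RT/accuracy
structure, and semantic relations between store names.  Passing recovery
tests therefore shows that the estimators measure what they claim under
the design's geometry and a realistic SNR — not that real tissue obeys
this generative model.

## Estimation

**LS-S single-trial maps.**  One GLM per trial: the trial of interest and
all other trials of the run as two HRF-convolved regressors, plus optional
extra event regressors, motion parameters, unit-impulse spike columns for
flagged frames, a DCT high-pass set (cutoff 100 s — the GLM equivalent of
the standard high-pass filter), and an intercept; correct active-baseline
periods stay unmodeled as the implicit baseline.  The per-voxel
t-statistic (OLS variance; prewhitening is deliberately not applied, and
`statistic = "beta"` exposes the raw coefficients) is the trial pattern.
The HRF is the SPM-style double gamma (gamma shapes 6 and 16, undershoot
ratio 1/6).  LS-S equals full-model OLS exactly for isolated trials and
converges to it as spacing grows; at the design's 18.13 s spacing the two
differ only through HRF overlap.  Degenerate inputs are contracts, not
accidents: all-zero series yield NaN t-values with a warning, and
rank-deficient designs fail naming the collinear columns.

**Run-level maps** model remembered and forgotten trials separately and
return the remembered-trials t-map, one per run (12 per subject), the
input to city classification.

**tSNR masks.**  tSNR = mean/SD (sample SD, n−1) of each voxel's series;
zero-variance voxels are excluded with a warning.  Level *p* removes
voxels strictly below the *p*-th percentile (linear-interpolation
quantile; ties kept), for p = 10..80; the eight kept sets are nested and
every ROI similarity result is the mean across the eight levels
(`averageAcrossTSNR()`).  Percentile convention, tie handling and SD
convention are all explicit because no standard fixes them.

## Similarity and decoding

**Pair rules.**  All similarity uses Pearson correlation on the kept
voxels (each pattern centered by its own mean — no z-scoring, exposed as
the natural Pearson default), Fisher-z transformed, averaged within
condition.  Holistic conditions pair store templates with trials as
described in the README.  Between-city conditions pair correct, uncensored
trials of *different* cities (hence always different runs): unique pairs
require disjoint store sets — the center store is ignored in that check,
since it belongs to every city — and shared pairs require identical store
sets (order-insensitive, matching the arrangement-permutation examples of
the design).  Within-task and cross-task pairs are pooled by default
(`task =` restricts).  Controls: `balance_pairs` equalizes condition pair
counts by seeded subsampling; `disjoint_pairs` thins pairs so no trial is
reused.  Degenerate zero-variance patterns are dropped and counted;
|r| is clamped at 1 − 1e−12 before atanh.

**Distance-uniformity trimming.**  The SVR requires a uniform distance
distribution; trials are removed one at a time (seeded) from the fullest
bin (ties toward the shortest distance) until a Kolmogorov–Smirnov test
against the discrete uniform over the reference bins exceeds α = 0.05.
The KS p-value is the asymptotic Kolmogorov series evaluated at √n·D with
D the largest ECDF gap at the bin atoms; `stats::ks.test` is not used
because it disowns ties, and the discrete reference is the package's
choice where the original procedure's flavor is unstated.  Reference bins
default to the distances observed in the input; if a reference bin is
empty, uniformity is unattainable by removal and the function says so
rather than exploiting the test's vanishing power at small n.

**Decoders.**  All classifiers are linear, via e1071/libsvm.  SVR: ε = 0.1,
C = 1, features unscaled by default (flags exposed); leave-one-city-out
folds; Fisher-z Spearman accuracy, chance 0.  Interval SVM: three classes
balanced by seeded subsampling in both training and test.  City SVM:
penalty 1, all 4³ = 64 one-run-per-city held-out combinations enumerated
and averaged (deterministic, superseding any sampled subset), prediction
by the highest class-probability estimate with a plain-prediction fallback
if probability fitting degenerates.  Fold structure never leaks the
held-out city/runs into training, and balancing/trimming are
seed-deterministic.

**Searchlight.**  Cubes of edge 7 (343 voxels) by default, clipped at
volume bounds and intersected with the mask; centers whose clipped cube
retains fewer than 50% of edge³ voxels return NA.  The statistic is an
arbitrary closure over the cube's trials × voxels matrix, so any of the
analyses above can be mapped.  Group-level corrected inference on the maps
is out of scope; the package checks localization (a planted 5³ effect's
peak within one cube edge) rather than cluster p-values.

**Same-location analysis.**  Between-city pairs whose triads occupy the
same three coordinate slots versus different slots, with the
different-location set matched to the same-location set on the number of
differing store identities (stratified; strata without matched pairs are
dropped with a message; the weighted contrast uses same-location stratum
sizes).  Identical-store pairs cannot occur in the different-location set,
so the zero-difference stratum drops automatically.

**Modulation statistics.**  Spearman partial correlation by ranking all
variables, residualizing x and y on the (ranked) controls, and
correlating residuals — symmetric, monotone-invariant, and equal to the
classic rank-partial formula for one control.  The analysis unit is the
within-subject template–trial (or trial–trial) pair, with group inference
by one-sample t over subjects and BH-FDR across conditions; the unit is
the package's choice where the original analysis is ambiguous, and a
subject-level mode is just `modulationGroupTest()` on per-subject results.

## Known limitations

- The hexagonal default layout yields 5 distinct distance indices, far
  fewer than an irregular realistic layout; distance-decoding results at
  desk scale rest on coarser bins than the original design's.
- Voxel noise is spatially white; searchlight false-positive behavior
  under smooth noise is untested.
- The LS-S variance is OLS, not prewhitened; t-maps under strongly
  autocorrelated noise are conservative-or-not depending on the design.
- e1071's probability estimates on 9-sample training sets are noisy; the
  city classifier averages 64 folds precisely to tame this.
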