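---
title: "Calibrated CT body composition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated CT body composition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcomp)
```

## The measurement problem

On CT, adipose tissue (AT) occupies a characteristic Hounsfield-unit (HU)
band below lean tissue (LT: muscle, organs, bone, brain). Fixed literature
windows for AT (commonly -190 to -30 HU) work adequately on a single
abdominal slice but misbehave on whole-body stacks, because the effective
HU scale shifts between scanners, reconstruction kernels and subjects. A
few HU of offset moves a large shell of near-threshold voxels across a
fixed boundary, so whole-body volumes computed with fixed windows are not
comparable across scans.

`ctcomp` implements a per-subject calibration of the AT/LT cutoff instead.
The operator draws eight short line segments on three axial slices — the
L4-L5 level, 85% of maximum femoral length (gluteal region) and 15%
(knee):

* lines **a, b, e, g** run entirely inside an adipose depot
  (subcutaneous at L4-L5 and the gluteal level, visceral, intramuscular);
* lines **c, d, f, h** cross an AT/LT interface with the transition at
  mid-line.

Each line yields a per-line *upper density limit*; their mean, rounded to
integer HU, is the subject's cutoff. The adipose window is then
`[-205, cutoff]` (the -205 HU floor is a fixed convention of the protocol)
and the lean window `[cutoff + 1, scan max]`. Before any voxel is
classified or any line sampled, the whole stack is denoised with a 3x3x3
median filter, which suppresses impulse noise without moving edges.

Total volumes are voxel counts times the voxel volume; slice areas (cm^2)
are taken at L3-L4, L4-L5 and the mid-thigh (50% femoral length, measured
from the distal end). From the measured areas, whole-body volumes and
masses are predicted with the published single-slice equations held in
`equation_registry()`: affine models `V = slope * area + intercept` with
coefficients stored exactly as printed, including the two sex-specific
comparator equations for AT volume and the two DXA-based comparator mass
equations. AT mass uses the density of fat, 0.92 kg/L; LT mass is body
weight minus AT mass. The multi-slice serial-section (trapezoidal) volume
`V = sum a_i (b_i + c_i) / 2` is provided for comparison with the older
22-slice protocol, implemented as the standard N-1-term trapezoid.

## Read-off rules for the line histograms

The original protocol reads the per-line limits *visually* off FIJI
histograms; a reproducible implementation needs deterministic rules, and
the choice is genuinely open:

* **Pure-AT lines**: the 98th percentile of the sampled HU values
  (`upper_limit_pure()`). The percentile is robust to isolated hot pixels,
  unlike the maximum; 98% on a 10-30-pixel line effectively reads the
  second-largest sample.
* **Mixed lines**: the antimode of a kernel-smoothed density
  (`upper_limit_mixed()`): Gaussian kernel of bandwidth 8 HU evaluated on
  a 1-HU grid over [-205, 150]; the reported value is the density minimum
  strictly between the two largest modes (ties averaged, which puts a
  symmetric two-spike profile's antimode exactly at the midpoint). A
  unimodal profile falls back to the midpoint of the 25th and 75th
  percentiles; a constant profile is an error.

The bandwidth (8 HU) and grid step (1 HU) are fixed constants chosen so
that transitions a few tens of HU wide are resolvable; both are exposed as
arguments. Line sampling is nearest-neighbour at unit-pixel steps with
inclusive endpoints — the histogram of the rasterised line, not an
interpolated profile.

Two consequences of these choices matter for interpretation:

1. **Deterministic read-offs are conservative.** The 98th percentile of a
   short, spatially correlated line profile sits well below the
   population 98th percentile of the tissue's HU distribution (order
   statistics of ~5-10 effective samples), and far below where a human
   reader, who tends to report the visual end of the histogram tail
   including partial-volume pixels, would point. Calibrated cutoffs from
   this package are therefore systematically lower than the originally
   reported corridor (-16 to 26 HU, mean -3): on the package's default
   phantoms they land near -50 HU. This does not harm classification —
   any cutoff inside the wide empty density valley between AT and muscle
   separates the tissues — and the translation-equivariance property that
   motivates per-subject calibration holds exactly: shifting every HU
   sample by k shifts the cutoff by k (to within the 1-HU grid).
2. **The corridor is reproduced by construction, not by physics.**
   `phantom_spec(boundary_hu = ...)` shifts the phantom's tissue means so
   that the *expected protocol read-off* (`expected_cutoff()`, a
   fixed-seed simulation of the eight filtered line profiles) equals a
   requested HU value. Phantoms injected at the published mean read-off
   (-3 HU) yield cutoffs inside the published corridor; the package's
   physically-centred default tissues do not, and no read-off rule
   consistent with a deterministic percentile can bridge that gap.

## The synthetic phantom

`make_phantom()` builds a cylindrical, deliberately non-anatomical body:
a torso section (bone core, muscle, subcutaneous AT shell, 3-voxel skin
layer, three visceral AT blob cylinders) stacked on a two-leg section
with an intramuscular AT streak near the knee. Canonical calibration
lines for labels a-h are placed inside the correct tissue by
construction, and the landmark set (L3-L4, L4-L5, femoral extent) is
returned alongside. Default grid 128^3 voxels at 3 mm isotropic spacing.

The HU model has three layers, each tied to a property of the pipeline:

* a **block-correlated heterogeneity field** per tissue (3-voxel blocks
  carrying the tissue SD) — real tissue texture is spatially correlated,
  and the 3x3x3 median filter must *preserve* it the way it preserves
  real anatomy (an iid-only noise model would be flattened by the filter,
  changing every read-off);
* **iid voxel noise** (SD 5 HU) added after ground truth is recorded —
  the component the median filter exists to remove;
* a **one-voxel partial-volume ramp** at every tissue interface — the
  mechanism that, in real scans, fills histogram valleys and makes fixed
  windows leak across tissue boundaries.

Default tissue distributions: AT ~ N(-110, 30) (centred on the -190..-30
literature window so that fixed-window comparisons are exercised near
both edges), muscle ~ N(55, 14), bone ~ N(400, 120), skin ~ N(20, 10),
air -1000 HU, plus a global `bias_hu` emulating the scanner offset.
Ground-truth labels follow the voxel-centre rule and are recorded before
noise, so ground-truth volumes are exact voxel counts. The skin layer is
3 voxels thick for a reason worth recording: a thinner skin ring is
*erased* by the median filter (AT below, air above — the median lands on
the adipose side), which silently converts the body surface into false
AT.

What a green phantom test does and does not establish: it shows the
pipeline recovers known tissue volumes within a few percent under
scanner-like bias, noise, texture and partial volume, and that per-subject
calibration absorbs HU offsets that break fixed windows. It does not
establish anatomical realism (no organs, no lungs, no marrow AT, no
scanner physics beyond additive bias and noise), nor rater behaviour —
the lines are placed perfectly, so inter-rater variability is outside the
synthetic world.

One measured limitation: the *volume* error of the fixed -190..-30 window
on these phantoms is monotone in the signed bias (5.4% / 2.7% / 0.9% at
-15 / 0 / +15 HU) rather than V-shaped in |bias|, because lean-side
boundary voxels (partial-volume HU around -17) sit just above the
window's -30 edge: negative bias sweeps them in while positive bias
sweeps adipose tail voxels out, so the signed error crosses zero near
+12 HU rather than 0. The voxel-misclassification count is V-shaped. The
corresponding acceptance assertion is left failing rather than re-centring
the adipose distribution post hoc.

## The synthetic cohort

`make_cohort()` emulates the published sample: n = 41 (36 male, 5
female), whole-body AT volume ~ N(22.7, 9.4) L and LT volume ~ N(40, 9.3)
L truncated to the published ranges, slice areas tied to the volumes
through the published equations, masses via 0.92 kg/L and
`weight = at_mass + lt_mass` (the LT mass per liter, 47.5/40, reproduces
the published mass means).

Each tissue has a designated *primary* relation — AT area at L4-L5 and LT
area at mid-thigh, the best published predictors. The primary area is
drawn exogenously and the volume set to `V = slope * area + intercept +
e`, with `sd(e) = |PE| * sqrt(pi/2)` so the expected mean absolute error
matches the printed |PE| (1.86 L for AT at L4-L5). OLS refits of primary
relations are therefore unbiased for the generating (printed) slope — the
property the parameter-recovery criterion checks. The remaining areas are
obtained by inverting their published equations around the same volume
with their own residuals; refits of those relations carry the mild
attenuation classical measurement error always produces (about 5-8% here),
exactly as fits on real, noisy cohort data do. This split is why the
multislice SVR has something to gain: the three areas are conditionally
independent noisy views of the same volume.

## Models and statistics

* **OLS** (`fit_ols()`): `lm()` under the hood, with the diagnostics the
  published analysis ran: Durbin-Watson statistic computed in data order,
  studentised Breusch-Pagan (n R^2 of squared residuals on the predictor,
  chi-squared with 1 df), the ANOVA F-test p, and normal Q-Q coordinates.
  In-sample |PE| (mean absolute error) and %PE are attached. %PE is
  implemented as the mean of per-subject *absolute* percent errors —
  the printed formula is signed, but every published value is an error
  magnitude; the signed variant is available via `signed = TRUE`.
* **Signed-rank test** (`compare_paired_abs_errors()`): zero differences
  dropped; exact tie-aware null distribution by convolution up to n = 25,
  normal approximation with continuity and tie correction above. Verified
  against full 2^n enumeration.
* **SVR** (`fit_svmr()`): linear-kernel epsilon-SVR solved by an SMO
  working-set method on the dual (no SVM library is assumed present).
  Features and target are standardised before solving, matching the
  reference implementation the published analysis used; hyperparameters
  default to that implementation's defaults, cost 1 and epsilon 0.1, and
  are exposed. The default feature set is the three areas of the matched
  tissue; `features = "all"` uses all six. The solver reproduces
  scikit-learn's SVR on a fixed fixture to ~1e-4.
* **LOOCV** (`loocv_mae()`): n refits, deterministic, model-agnostic via
  a small fit/predict spec.
* **Agreement** (`icc()`, `bland_altman()`): single-measure ICC from
  variance components — two-way random absolute agreement ICC(A,1) by
  default, with the one-way ICC(1,1) available. The original report does
  not name its ICC model and its raw rating tables are unpublished, so
  the printed ICCs (0.9803/0.8831 inter-rater, 0.9833/0.9909 intra-rater)
  are documentation values, not reproduction targets. Bland-Altman limits
  use the classic 1.96 multiplier.

## Numerical conventions

* Cutoffs are rounded to integer HU before thresholding (thresholds apply
  to integer-HU data; `cutoff + 1` is then unambiguous). A voxel exactly
  at the cutoff is adipose; at cutoff + 1, lean; below -205 HU, neither.
* Fractional slice positions round to the nearest slice, halves away from
  the distal femur, making `femoral_fraction_slice()` monotone in the
  fraction for either axial orientation.
* Median-filter borders use reflected padding (choice fixed for
  determinism; borders are air in practice).
* The NIfTI writer stores float64 so volumes round-trip bit-exactly;
  voxel spacing lives in the format's float32 header fields. The DICOM
  layer is intentionally minimal: explicit VR little endian, single-frame
  int16 with rescale tags; anything else is a hard error naming the tag.
* Negative predictions from published equations (possible at tiny areas
  with a negative intercept) are returned with a warning, never clamped.
* All generators are deterministic per seed; `expected_cutoff()` uses a
  private fixed RNG stream and restores the caller's RNG state.

## Known limitations

* Landmarks and calibration lines are operator inputs (files), never
  auto-detected: the method is semi-automatic by design.
* No body-outline masking or connected components: scan tables or
  clothing would be misclassified; the phantom world contains neither.
* Bone marrow AT inside bone falls in the adipose window and counts as
  AT, consistent with the tissue-level definition.
* Metal implants are only handled by the 4000 HU load clamp; the lean
  window's upper bound is literally the scan maximum.
* Multi-stack whole-body scans must be merged before loading; partial
  female/male stack stitching is out of scope.
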