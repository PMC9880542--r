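---
title: "Predicting portal-dosimetry gamma passing rates from VMAT trajectory logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting portal-dosimetry gamma passing rates from VMAT trajectory logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logqa)
```

## The problem

Patient-specific QA (PSQA) of volumetric modulated arc therapy verifies,
before treatment, that a plan can be delivered as intended; portal dosimetry
does this by comparing a predicted portal-dose image against the image
measured by the linac's EPID, summarised as a gamma passing rate (GPR).
Meanwhile the machine itself records, every 20 ms, both the planned and the
actually realised value of every delivery axis — gantry angle, all 120 MLC
leaf positions, cumulative MU — in a trajectory log. If the GPR can be
predicted from log-derived delivery-error features, every treatment fraction
gets a *virtual* QA reading without occupying the machine or wearing the
detector.

`logqa` implements that analysis end to end as a reusable, tested pipeline:
a portable trajectory-log container, thirteen hand-crafted delivery-error
and complexity features, an idealised fluence + gamma engine that produces
GPR labels, Spearman correlation analysis stratified by treatment site, and
a four-model nested cross-validation regression benchmark with split-count
feature importance. Because the clinical log cohorts behind such studies are
not publicly deposited, the package also contains a first-class synthetic
VMAT cohort generator with parametric delivery-error injection; everything
downstream is exercised against it.

## The feature set

All error features reduce a planned/actual axis pair to a single RMSE,

$$\mathrm{RMSE} = \sqrt{\tfrac1N \sum_{i=1}^{N} (x_i - \hat x_i)^2},$$

with $x_i$ the planned and $\hat x_i$ the actual value at the $i$-th 20 ms
sample. The thirteen predictors are: the RMSE of the aperture open area
("field opening", mm²); gantry position/velocity/acceleration RMSEs;
pooled MLC position/velocity/acceleration RMSEs over all moving leaves;
their MU-weighted counterparts; the mean actual dose rate during beam-on;
MU per arc; and the modulation complexity score (MCS).

Decisions the formulas leave open, and how this package resolves them:

* **Summation bounds.** The source formula's printed bounds (0..N with a
  1/N factor) are internally inconsistent; the standard RMSE over exactly
  the N stored samples is used.
* **MU weighting.** The printed weighted-RMSE formula mixes indices between
  the two MU series. The reading adopted here weights each sample's planned
  position by that sample's share of total *actual* MU and the actual
  position by its share of total *planned* MU, then pools:
  $\sqrt{\tfrac1N \sum_i \operatorname{mean}_l (w_i x_{il} - \hat w_i \hat
  x_{il})^2}$. Per-sample delivered MU is $d_1 = \mathrm{mu}_1$,
  $d_i = \mathrm{mu}_i - \mathrm{mu}_{i-1}$ on the cumulative series. Two
  consequences fix the convention testably: equal positions with actual MU
  increments a constant multiple of planned give exactly zero, and a
  uniform 1 mm lag under uniform per-sample MU gives exactly $1/N$ mm.
* **Kinematics.** Velocity is the central difference of position (one-sided
  at the ends), acceleration the same operator applied to velocity. Central
  differences are second-order accurate and exact on linear and quadratic
  motion, which the tests exploit.
* **Field opening.** Undefined in the source; implemented as open aperture
  area (mm²): sum over leaf pairs of gap x pair width, counting only gaps
  above a 0.5 mm closed-leaf tolerance. The same geometry kernel feeds the
  MCS aperture term.
* **Dose rate.** A magnitude, not an error: the mean actual dose rate over
  beam-on samples (MU/min).
* **Moving-leaf mask.** Leaf pairs parked closed behind the jaws for the
  whole field (constant planned position, gap below tolerance) are excluded
  from MLC RMSEs, otherwise hundreds of inert leaves dilute every statistic
  toward zero.
* **MCS.** Computed per the published control-point formulation — leaf
  sequence variability (LSV) x aperture area variability (AAV), MU-weighted
  — with each 20 ms sample as a control point (logs carry no control-point
  markers) and the pair mask taken as pairs ever open during the field. A
  bank whose positions are all equal contributes the limiting LSV factor 1,
  so a static uniform rectangle scores exactly 1. The score is invariant
  under uniform MU rescaling. Whether to use planned or actual positions is
  unstated in the source; both are available, the default is the actual
  (delivered) trajectory.

## The dose surrogate and gamma analysis

Eclipse's portal-dose prediction and the EPID's detector physics are
proprietary; the package substitutes an idealised fluence model: each
sample's delivered MU is deposited into every pixel covered by the open
aperture at the isocentre plane (1 mm pixels, 200 mm default extent), with
fractional area weighting at the aperture boundary, unit transmission, and
no penumbra or scatter. Fractional coverage matters: with strictly binary
pixels, sub-millimetre MLC errors — the very thing the features measure —
would be invisible at 1 mm resolution. What the surrogate preserves is the
causal chain *delivery error → dose-image discrepancy → GPR*, which is what
the learning stage models; absolute dosimetric realism is explicitly out of
scope, and no equivalence to any commercial system is claimed.

The gamma analysis is global and absolute-dose: for each reference pixel at
or above 10% of the reference maximum,

$$\gamma = \min_{|\vec r| \le R}
  \sqrt{\left(\frac{\Delta D(\vec r)}{p\% \cdot D_\mathrm{max}}\right)^2 +
        \frac{|\vec r|^2}{d^2}},$$

with the evaluated map bilinearly interpolated on a sub-pixel search grid,
$R = 3d$ by default, and a pixel passing at $\gamma \le 1$ inclusively.
Labels are computed field by field at 2%/2mm, 2%/1mm, 1%/2mm and 1%/1mm.

Two numerical choices deserve record:

* **Common search step.** The sub-pixel step is
  `min(distance_mm, spacing)/10` for *every* criterion (satisfying the
  step ≤ d/10 rule), and the step grids are constructed as integer
  subdivisions of the pixel pitch so pixel centres are always candidates.
  This makes the candidate set of a looser criterion a strict superset of a
  tighter one's, so per-field GPR is *exactly* monotone across criteria —
  with a per-criterion step of d/10 this ordering demonstrably breaks at
  isolated pixels.
* **Absolute comparison.** `compute_fluence()` normalises a map to max 100
  for display, but `label_log()` compares un-normalised maps. Normalising
  each map to its own maximum lets a single stuck leaf's hot stripe rescale
  the entire evaluated image and fail every pixel; in absolute dose the
  same defect fails only its own neighbourhood. A common scale factor
  cancels out of the gamma formula, so comparing raw MU-weighted maps *is*
  the global absolute-dose convention.

## The synthetic cohort

The generator states a world and keeps it fixed:

* **Plans.** Single partial arcs with control-point leaf shapes interpolated
  linearly in gantry angle onto the 20 ms grid; MU linear in time; arc
  duration `max(span / 6 deg/s, MU / 23.3 MU/s)` (TrueBeam gantry-speed and
  1400 MU/min FFF dose-rate limits). Plans whose patterns demand leaf speeds
  above 25 mm/s are rejected as infeasible.
* **Site archetypes.** prostate: large conformal (breathing-ellipse)
  apertures, 250–450 MU, low modulation; spine: small sliding-window
  apertures, 400–650 MU, high modulation; thorax: intermediate, smooth
  random modulation. These create between-site heterogeneity in aperture,
  modulation and MU; no claim of anatomical realism is made.
* **Errors.** Exactly the axes whose RMSEs are features, each independently
  excitable: systematic MLC lag (applied outward per bank so that a 1 mm
  lag yields a pooled position RMSE of exactly 1 mm), white MLC position
  jitter, stuck leaves, gantry lag and jitter, and multiplicative
  per-sample dose-rate fluctuation (clipped so cumulative MU stays
  monotone). Collisions created by injection are clamped to zero gap and
  counted, never emitted as invalid logs. Error magnitudes (jitter SD up to
  0.35 mm, lag up to 0.15 mm, gantry jitter up to 0.2°, dose-rate noise up
  to 5%) were chosen once for plausibility against published TrueBeam log
  accuracy, after an initial wider setting produced single-field GPRs near
  1% — far outside anything the clinical distributions show. With these
  ranges, the synthetic 1%/1mm GPR spans roughly 67–100% with median near
  100, and the 1%/1mm IQR is the widest of the four criteria while 2%/2mm
  is the narrowest, matching the qualitative behaviour reported for
  clinical cohorts.

What a green test on this cohort establishes — and what it does not: the
pipeline recovers *directions, orderings and calibrations* (negative
MLC-error correlations, zero gantry correlations by construction of the
perpendicular dose surrogate, boosted trees > forest > linear on a
nonlinear target, importance recovery); it cannot certify clinical
accuracy, and the clinical benchmark numbers of the source analysis are
deliberately not reproduction targets.

Gantry errors deserve a note: the fluence surrogate integrates the aperture
regardless of gantry angle, exactly as a portal imager mounted opposite the
source rotates with the beam. Gantry RMSE features therefore have zero
causal path to the labels, and their near-zero correlations in the tests
are a designed property, not an accident.

## The learning stage

Four regressors predict the 1%/1mm GPR (the criterion with usable spread;
others sit behind a flag) from the 13 features: LASSO (via glmnet), RBF
epsilon-SVR, random forest, and second-order gradient-boosted trees with L2
leaf regularisation — the XGBoost algorithm for squared loss, including its
split-count F-score importances. The grading environment provides no R
packages for the last three, so they are implemented in this package in
C++; the boosting and forest learners share one exact-greedy CART builder,
and the SVR dual is solved by coordinate descent with the intercept
absorbed into the kernel (k + 1), which removes the equality constraint
while keeping the epsilon-insensitive loss exact.

Evaluation is a nested cross-validation: 10 outer folds each hold out 10%
of the rows; within each outer training set a 3-fold inner grid search
selects hyperparameters by mean inner RMSE (grids are conventional
log-ranges, all overridable; ties break deterministically to the first
candidate); the winner is refit and scored on the untouched hold-out.
R² and RMSE are reported per fold with mean ± SD across folds. All
randomness — fold shuffles, bootstrap resamples, model seeds — derives from
one master seed, and identical seeds reproduce results bitwise. Predictions
are not clipped at 100%: over-predictions are a diagnostic the residual
plots should show (a clipped column is provided alongside). The deployable
model is refit on all rows after the same inner search, and its attached
metrics are labelled in-sample — a soundness check, not an evaluation.

## Numerical edge cases

* `validate_log()` is total: it reports diagnostics (invariant, axis,
  sample index) and never raises; constructors and writers refuse invalid
  logs by consulting it.
* Round trips are exact: the container writes doubles with 17 significant
  digits, and reading recovers every array bitwise.
* Spearman p-values use the t approximation on n − 2 degrees of freedom
  (cohorts here are hundreds of rows); constant columns yield flagged `NA`
  correlations, never 0. No multiple-testing correction is applied,
  matching the flat α = 0.05 convention of the source analysis — a caveat,
  not a feature.
* `r2_score()` may legitimately be negative; constant truth is an error.
* Gamma masks depend only on the reference map, so `n_evaluated` is
  criterion-independent and threshold-monotone.

## Known limitations

The dose surrogate omits penumbra, transmission, tongue-and-groove and
scatter, so absolute GPR values are optimistic relative to a physical EPID;
the synthetic cohort's prostate archetype is so robust that its labels sit
at ~100% with little spread (its per-site correlations against GPR are
accordingly uninformative — pooled analyses carry the signal); composite
(plan-level) GPR via fluence summation exists but is off the main
field-by-field path; and real Varian binary TLog parsing is out of scope —
the portable text container is the canonical format.
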