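---
title: "Shape scoring of tumor compartments: methods and design notes"
author: "mppscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape scoring of tumor compartments: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The score

For a two-dimensional region with perimeter $P$ and area $A$, the
Polsby–Popper score

$$PP = \frac{4\pi A}{P^2}$$

is the classic isoperimetric quotient: it equals 1 for a perfect circle
(the most compact shape for a given area) and tends to 0 as the boundary
becomes wavier or the region breaks into disjoint islands. Tumor
compartments on histology sections are exactly the kind of object whose
"waviness" and "disjointedness" carry biological meaning — an undulating
invasive front and scattered satellite islands are hallmarks of
aggressive growth — so the package scores the *reciprocal* quotient on a
log scale:

$$MPP = \tfrac{1}{2}\,\ln\frac{P^2}{4\pi A} = -\tfrac{1}{2}\,\ln PP .$$

A circle scores 0 and scores grow without bound with increasing boundary
complexity. The logarithm matters statistically: slide-level $P^2/4\pi A$
ratios are approximately log-normal, so the transformed score is
approximately normal and fits the downstream t-tests, ANOVAs and
correlations. The natural logarithm is used throughout; any other base
would only rescale the score. Note that some descriptions place the
reciprocal quotient itself (range $[1,\infty)$, circle at 1) rather than
its half-log (range $[0,\infty)$, circle at 0) at the centre of the
method; the two disagree only by the monotone transform, and this package
implements the half-log form consistently, so a circle scores exactly 0.

Two properties drive the design of everything else:

* **Scale invariance.** $MPP(sP, s^2A) = MPP(P, A)$: magnification does
  not change the score, so it can be compared across slides scanned at
  different resolutions (the *measurement* of $P$ is not scale-free,
  though — see "Resolution dependence" below).
* **Fragmentation additivity.** If a region is replaced by $n$ congruent
  disjoint copies with the same total area, the score of the totals rises
  by exactly $\tfrac12\ln n$. This is why the package aggregates by
  summing perimeters and areas over *all* regions of a class on a slide
  and scoring the totals; averaging per-region scores would erase the
  disjointedness signal entirely (`aggregateMPP`).

## Measuring $P$ and $A$

Polygon annotations (the format digital-pathology viewers export as
GeoJSON) are measured exactly: shoelace area of the outer ring minus hole
areas, edge-length sums for the perimeter. Hole boundaries *count toward
the perimeter* and hole areas are subtracted: a stroma-filled cavity
inside a tumor compartment is tumor/host interface, which is precisely
what the score is meant to capture. Whether the original viewer exports
counted hole boundaries is not documented anywhere we know of; this is a
deliberate package decision, applied consistently to polygons and rasters.

Raster masks are traced at the 0.5 iso-level of a Gaussian-presmoothed
copy of the binary indicator, one 4-connected component at a time
(`extractRegions`). Tracing the raw binary grid would be badly biased:
marching-squares contours of unsmoothed binary data overestimate the
perimeter of a digitized disk by about 5% (and pixel-edge counting by up
to 27%), which would inflate every MPP. The smoothing bandwidth defaults
to

$$\sigma_{px} = 1.5\sqrt{\text{resolution (px/µm)}}$$

(floored at 0.75 px). The square-root scaling is chosen so that both
error components vanish as resolution grows: the grid-roughness error
falls as $\sigma_{px}$ grows, while the physical smoothing bias falls as
$\sigma_{px}/\text{resolution}$ µm shrinks. With this rule a radius-200 px
disk measures $PP = 0.997$, and the raster-vs-quadrature MPP error of the
wavy-disk family decays monotonically with resolution (the test suite
checks 0.5, 1 and 2 px/µm). Raster noise can push a measured $PP$
marginally above 1; values within 0.02 of 1 are clipped to 1 (MPP floor
0) with a warning, anything larger is treated as a geometry error.

Regions are returned in a deterministic order (decreasing area, ties by
topmost-then-leftmost vertex), and a configurable minimum-area filter
drops classification specks, which otherwise dominate perimeter totals.
The pipeline default for that filter is the area of one default
superpixel (2500 µm² at 50 µm spacing); the bare `measureClass()` call
defaults to 0 so that nothing is filtered implicitly when measuring
hand-built fixtures.

## Resolution dependence

The measured perimeter of a wavy boundary depends on every
resolution-type parameter of the pipeline — raster resolution, superpixel
size, annotation granularity. The score is therefore comparable *within*
a cohort processed with one configuration, not across configurations.
`mppSpacingProfile()` makes this visible by reporting the score at half,
nominal and double superpixel spacing side by side.

## The segmentation stage

The tissue-detection stage emulates, at desk scale, the semiautomated
workflow used on whole-slide images: superpixel segmentation, intensity
features, supervised classification from example regions, and merging of
same-class superpixels into annotations.

* `computeSuperpixels()` is a SLIC-style local k-means in joint
  color+position space: grid-seeded centres at step $S$ (spacing in µm /
  pixel size), assignment within a $2S$ window under
  $d_{color}^2 + (d_{xy}/S)^2 m^2$ with color on a 0–255 scale and
  compactness $m = 10$, ten sweeps, then a connectivity pass that merges
  stray fragments into the adjacent superpixel with the longest shared
  border. Merges are resolved against the pass-start state so fragments
  cannot chain into elongated superpixels. As in the original SLIC
  construction, the image is pre-smoothed with a 1-px Gaussian before
  clustering; without it, pixel noise makes the recovered boundaries
  ragged enough to inflate the MPP of a recovered compartment by ~0.2.
* Features per superpixel: mean and SD of each channel plus mean
  grayscale, with z-scored copies standardized over the ROI. "Intensity
  features" is all the emulated workflow promises, and these suffice for
  the synthetic images.
* `trainTissueClassifier()` replaces an iterative, visually supervised
  retraining loop — which has no reproducible stopping rule — with a
  single supervised pass: superpixels are labeled by their largest
  scribble overlap and a nearest-centroid rule is fitted on the
  standardized features. Deterministic, and upgradeable behind the same
  interface.
* `classifyAndMerge()` paints predictions back onto the pixel grid and
  traces each 4-connected same-class component into a polygon annotation,
  which feeds `measureClass`/`scoreClass` directly. The stromal ratio
  $100\cdot A_{stroma}/(A_{stroma}+A_{tumor})$ sums the fibrous and
  lymphocytic stroma classes (`stromaTumorRatio`).

## Synthetic data: what it emulates, and what it does not

All test inputs are generated in code.

**Wavy disks** ($r(\theta) = R(1+\varepsilon\sin m\theta)$, simple for
$\varepsilon < 1$) have closed-form area $\pi R^2(1+\varepsilon^2/2)$ and
a quadrature perimeter (adaptive, relative tolerance $10^{-8}$), so every
raster measurement can be checked against an independent oracle. The MPP
of the family increases strictly in $\varepsilon$ and in $m$, which makes
it a useful stand-in for "compact" versus "wavy" invasion fronts.

**Satellite masks** add disjoint circular islands at least 1 mm (the
defining distance for a discontinuous infiltration pattern) from the main
mass, with analytic totals; fragmentation additivity gives exact expected
scores (a main circle plus one equal satellite scores $\tfrac12\ln 2$).
Tests of these masks run at 0.25 px/µm so that millimetre gaps fit in a
~1000² px canvas.

**Histology images** paint each class in an H&E-like base color, add
Gaussian pixel noise (default SD 0.05) and a smooth ±5% illumination
field, and can carve a requested stroma fraction out of the tumor
compartment by thresholding a smoothed noise field at the matching
quantile — so the ground-truth stromal ratio is exact by construction.
The carved septa have a physical characteristic scale (default 150 µm,
the order of real stromal bands); structures much finer than a superpixel
cannot be recovered by any superpixel classifier, and the defaults keep
the fixture in the regime the method is meant for. These images contain
no nuclear morphology, texture, or stain variation: passing the
end-to-end tests shows the pipeline recovers geometry from
well-contrasted compartments, not that it segments real H&E tissue.

**The synthetic cohort** (`generateCohort`) reproduces the statistical
skeleton of a 100-case tongue-carcinoma cohort: composition 40/39/17/4
over pT1/pT2/pT3/pT4a; per-group Gaussian MPP marginals (3.39 ± 0.65,
4.04 ± 0.46, 3.94 ± 0.54, 4.33 ± 0.42) and tumor-thickness marginals
(4436 ± 2759, 8776 ± 3446, 9267 ± 2549, 11436 ± 2017 µm). MPP and
thickness are coupled through a Gaussian copula whose *within-case*
latent correlation is solved analytically at configuration time so that
the *pooled* correlation equals the configured 0.736 — the group mean
structure already carries part of the pooled signal, so the latent value
(≈0.657) is smaller. MPP is truncated at 0 by joint resampling
(negligible mass); thickness is floored at 1 µm rather than resampled,
because resampling on the thickness tail would bias the MPP marginal
through the copula (~2% of pooled draws are affected; the pT1 thickness
mean shifts up slightly, which the tests allow for).

Survival uses competing piecewise-exponential hazards with knots at 24
and 60 months, the minimal structure that passes exactly through two
printed anchors per stratum: the tumor-specific death hazard comes from
the tumor-specific survival anchors of each MPP stratum (split at 4.2),
the other-cause hazard is the overall-survival-implied hazard minus the
tumor-specific one, so both endpoint calibrations hold jointly; the tail
beyond 60 months reuses the middle-piece hazard. Recurrence uses one
pooled hazard for both strata (no stratum-specific anchors are published
and the reported difference was not significant), and the
distant-metastasis hazard is zero in the low stratum (no events were
observed there) and anchored at a 5-year survival of 0.707 in the high
stratum. Administrative censoring is uniform on (2.2, 185) months, which
gives a reverse Kaplan–Meier median follow-up of 93.6 months and a
maximum of 185. Categorical labels (grade, nodal status, growth and
infiltration patterns, margin stratum) come from latent-liability models
tied to the pooled MPP z-score with association strengths chosen to
reproduce the published label-group MPP mean differences; they are
plausibility devices, not fitted models. Likewise the emulated
pathologist's stromal estimate (truth + N(0, 7 pp), configurable) is a
plausibility value, not a fitted observer model. The generator does not
model treatment effects, competing-risk dependence beyond the shared
stratum, or non-proportional hazards.

## The statistics layer

Biomarker dichotomization uses the linear-interpolation (type-7) sample
quantile, by default the 75th percentile, with *strictly greater*
defining the high group. Kaplan–Meier estimation, Greenwood bands and the
log-rank test (hypergeometric tie handling) are delegated to the
`survival` package behind the package's own interfaces; the reverse
Kaplan–Meier follow-up estimator swaps event and censoring indicators.
With more than two groups the log-rank test is followed by pairwise
chi-squared post hoc comparisons, reported unadjusted by default (an
optional Bonferroni flag exists) — multiplicity handling in the emulated
workflow is not documented, so the package makes the unadjusted choice
explicit. Two-group comparisons use Welch's unequal-variance t-test
(fractional degrees of freedom) with Cohen's *d* on the pooled SD — the
*d* variant is not determined by the emulated workflow either, and pooled
is the conventional default. More than two groups get a one-way ANOVA
with $\eta^2 = SS_{between}/SS_{total}$. Endpoint derivation from raw
event records follows the standard rules: deaths from other causes censor
tumor-specific survival at the death date; recurrence-free death censors
relapse-free survival; all clocks start at surgery.

Paired ROC-AUC comparison uses the DeLong structural-components method
with the fast mid-rank algorithm as implemented in `pROC` (AUCs,
variances and covariance; two-sided z-test on the difference). The test
suite cross-checks the variance against jackknife and stratified
bootstrap oracles on a fixed n = 30 fixture. Cox multivariable regression
and machine-learning model training are deliberately out of scope; the
comparison accepts any externally produced score vectors.

## Numerical choices and degenerate inputs

* Contour smoothing $\sigma_{px} = \max(0.75, 1.5\sqrt{px/µm})$; contours
  traced with `grDevices::contourLines` on a padded window per component.
* $PP > 1 + 10^{-9}$ clipped with a warning up to $1+0.02$, error beyond.
* Degenerate rings (< 3 distinct vertices, zero area) and holes at least
  as large as their outer ring are rejected as invalid geometry.
* Quantile thresholds need at least 4 finite values; groups need
  $n \ge 2$ per group; correlations need $n \ge 3$ and non-zero variance.
* Survival anchors must be non-increasing in time; infeasible pooled
  correlations (latent $|\rho^*| \ge 1$) are a configuration error.
* Region extraction after smoothing erases isolated specks smaller than
  about $\sigma$ px across; this is intentional and consistent with the
  minimum-area filter's purpose.
* Ties in nearest-centroid classification and region ordering break
  deterministically (first class, smallest label, topmost-leftmost
  vertex), so every pipeline output is reproducible byte for byte under a
  fixed seed.

## Problem sizes used by the tests

The test suite and the acceptance script are sized for a laptop-class
run: raster oracles up to a 1000²-px disk, wavy-disk convergence at 0.5/1/2
px/µm, 100-circle fragmentation grids, segmentation fixtures of ~260² px
with ~100–450 superpixels, 200–1000 replicate cohorts of n = 100 for the
threshold and correlation checks, and 2000-replicate null simulations for
the type-I-error checks. These sizes are the package's own choice of
desk-scale study conditions; all of them can be scaled up through the
exported functions.

## Known limitations

* The MPP score conflates waviness and fragmentation by design; it cannot
  distinguish one very wavy region from many compact ones at the same
  total $P^2/A$.
* Raster measurements inherit a resolution dependence that no smoothing
  rule removes entirely; compare scores only within one configuration.
* The nearest-centroid classifier is a deliberately simple stand-in for
  interactive tissue detection; real H&E material needs stain
  normalization and richer features, which are out of scope here.
* The cohort generator reproduces marginals, one pooled correlation,
  stratum-level survival anchors and label-group mean differences — not
  the full joint distribution of a real clinicopathologic dataset.
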