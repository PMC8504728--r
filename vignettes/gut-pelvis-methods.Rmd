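---
title: "Methods: landmark pelvimetry, gut volumetry and sex-specific allometric inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark pelvimetry, gut volumetry and sex-specific allometric inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelvimetrics)
library(dplyr)
```

This vignette is the package's own account of its methods: the measurement
model, the statistical machinery, the synthetic-data generator that stands
in for an unavailable CT cohort, and the numerical and design choices made
where more than one defensible option existed.

## The measurement model

The true pelvis is summarised by 11 named 3D landmarks (paired ischial
spines and tuberosities, three sacral points, two dorsal pubic symphysis
points, and the paired widest points of the iliopectineal lines). From
these, `canal_measurements()` computes:

* six linear dimensions as Euclidean interlandmark distances (ILDs):
  inlet AP (promontory to dorsal superior symphysis) and ML (between the
  iliopectineal points), midplane AP (S4/S5 to dorsal inferior symphysis)
  and ML (between the ischial spines), outlet AP (S5 apex to dorsal
  inferior symphysis) and ML (between the ischial tuberosities);
* three shape indices, each plane's AP divided by its ML (dimensionless;
  below 1 is transversely wide, above 1 sagittally long);
* two angles of the "spine triangle" formed by the S5 apex and the two
  ischial spines: θ_a at the S5 apex (smaller means the spines project
  more medially into the canal) and θ_b at the **left** ischial spine
  (larger means the sacrum sits farther from the spines).

Three choices deserve comment.

**Angles come from distances, not vectors.** θ_a and θ_b are computed
from the three ILDs of the spine triangle by the law of cosines, mirroring
how the triangle is constructed from distance measurements in practice.
The equivalent vector/dot-product computation exists in the test suite
only, as an independent oracle; the two agree to well below 1e−9 degrees
on non-degenerate triangles, and the three triangle angles sum to 180°.

**θ_b is left-vertex by definition.** The angle is defined at the left
ischial spine. Left/right asymmetry of a specimen is therefore visible in
θ_b; we deliberately do not symmetrise or average with the right-vertex
analogue, so the reported value matches the definition exactly.

**No axis frame is assumed.** Coordinates are millimetres in an arbitrary
right-handed scanner frame. Every reported measure is invariant to rigid
rotation and translation (verified against a vector-geometry oracle on
randomised configurations) and angles and shape indices are additionally
scale-invariant.

Degenerate geometry is an error, never a clamped value: triangles whose
sides violate the triangle inequality beyond a relative slack of 1e−6
raise an inconsistent-distances error, and collinear configurations
(slack within 1e−6 of zero) raise a degenerate-geometry error. Returning
a silently clamped 0° or 180° would poison downstream log-scale
regressions.

## Gut volumetry

`gut_volume()` implements slice-summation CT volumetry: the segmented
intestinal area of each binary mask slice (positive-pixel count × pixel
footprint) is multiplied by the slice thickness and summed, then reported
in cc. Two modelling rules are fixed:

* **Slab model.** A slice's mask is treated as constant through the full
  slice thickness (5 mm by default, the study geometry); there is no
  inter-slice interpolation. This is exactly what area × thickness
  summation implies.
* **Centre rasterisation.** In validation phantoms a pixel is inside the
  solid iff its centre is inside, which is asymptotically unbiased for
  convex solids; slice slabs tile the solid's z-extent symmetrically
  about its centre, so a solid spanning m slabs is sampled at m mid-slab
  planes and a solid thinner than one slab sits at a slab centre.

With these rules a 20 mm-radius, 50 mm cylinder phantom is recovered
within 0.6% at 1 mm pixel spacing (the residual is in-plane rasterisation
error; the z-direction is exact for slab-aligned cylinders), and the error
never grows as the grid is refined. Spheres at 5 mm slices carry a few
percent of z-discretisation error, as expected of first-order slab
sampling. The module consumes masks and is agnostic about what was
contoured (lumen plus wall or lumen only); segmentation itself is out of
scope.

## Observer reliability

`icc_absolute_agreement()` is the two-way crossed, absolute-agreement,
single-rater intraclass correlation,

$$\mathrm{ICC} = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with the F-based confidence interval using Satterthwaite degrees of
freedom. The absolute-agreement form penalises systematic rater offsets,
not just inconsistency — adding a constant to one observer's column
strictly lowers the estimate. Interpretation bands are closed on the
left: excellent ≥ 0.90, good ≥ 0.75, moderate ≥ 0.50.

Three interpretive decisions: the conventional 95% confidence interval is
reported for the agreement's "tolerance"; the single-rater (not
average-of-raters) form is used because agreement is assessed on a
measurement by an individual observer; and subjects with any missing
rating are dropped listwise, with the count reported. Ratings matrices
with zero between-subject variance raise an explicit undefined-ICC error
rather than returning 0/0.

The fuzzy-landmark rule (`average_fuzzy_replicates()`) handles
measurements built on landmarks with no crisp anatomical point — by
default the outlet ML diameter, whose ischial-tuberosity landmarks are
hardest to replace reproducibly. Such measurements are digitised in
replicate and arithmetically averaged; all other fields must agree across
replicates within a relative tolerance of 1e−6 or an error names the
offending field. The outlet shape index is recomputed from the averaged
OML rather than averaged as a ratio, so the AP/ML identity survives
averaging.

## Sex-specific inference

All variables — gut volume, body weight, linear dimensions, shape indices
and angles — are natural-log transformed before fitting. The base is a
pure reporting convention (it rescales coefficients, never p-values or
R²). Angles are log-transformed like everything else for consistency of
the transform across responses; because angles are not ratio-scale in the
same sense as lengths, the fitting functions accept any numeric response
column, so a raw-angle analysis is a one-line variation.

The model forms are asymmetric by design: males use
`response ~ GV * weight` because male gut volume scales allometrically
with body weight (the predictors are structurally entangled), females use
`response ~ GV + weight` because female GV and weight are independent.
`compare_interaction()` provides the nested-model F-test showing the
female interaction term is dispensable; under a null generator its
rejection rate sits at the nominal 5%, and a degenerate (aliased or
constant) interaction column raises an error rather than a silent p = 1.

Reporting conventions:

* The headline "R²" is **adjusted** R² — it can legitimately be negative
  for uninformative models, and the raw R² is reported alongside because
  it is what the relative weights decompose.
* Coefficient p-values are two-sided marginal t-tests from the fitted
  model.
* Flags are two-level and inclusive: `**` for p ≤ 0.01 (the conservative
  primary alpha) and `*` for 0.01 < p ≤ 0.05. No multiple-testing
  correction is applied across the 11 responses; the tightened primary
  alpha plays that role, and the number of fitted models is attached to
  the report as the `n_tests` attribute.
* Relative weights are computed on the two main predictors (log GV, log
  weight) for both sexes, excluding the male interaction term, so that
  exactly two percentages sum to 100 per model. How to attribute an
  interaction's share of R² is genuinely ambiguous; tying the
  decomposition to the main effects keeps the male and female columns
  comparable.

The relative-weights decomposition itself is the Johnson ε method: with
predictor correlation matrix $R_{xx} = V \Lambda V'$ and its symmetric
square root $\Delta = V \Lambda^{1/2} V'$, the transformed coefficients
are $\beta^* = \Delta^{-1} r_{xy}$ and the raw weights
$\varepsilon = (\Delta \circ \Delta)(\beta^* \circ \beta^*)$. The raw
weights are non-negative and sum to the regression's raw R² exactly
(machine precision; enforced in tests to 1e−10), percentages sum to 100,
and under exactly orthogonal predictors each weight reduces to the
squared predictor-response correlation.

For display, `bodymass_groups()` reproduces the ±1 SD body-mass grouping
(low strictly below mean − 1 SD, high strictly above mean + 1 SD, per
sex), and `plot_canal_regression()`/`autoplot()` draw the grouped
scatter-plus-fit-lines panels.

## The synthetic-data generator

No specimen-level data accompany the study design, so the generator
(`generator_config()`, `simulate_cohort()`, `simulate_landmarks()`,
`simulate_mask_stack()`) is a first-class module that emulates the
cohort's *statistical structure* with every effect size known and
configurable:

* **Marginals.** Body weight per sex and female GV are normal (truncated
  at zero), parameterised by the published descriptive statistics
  (80.43 ± 19.27 kg and 5384 ± 1320.86 cc male, 67.17 ± 13.15 kg and
  4192.13 ± 912.44 cc female; statures 1.77 ± 0.07 / 1.64 ± 0.07 m).
  Mean ± SD is all the descriptives constrain, so normality is the
  neutral choice; truncation matters only in the far tail.
* **Allometry.** Female GV is independent of weight. Male GV follows
  log GV = a + 0.8·log W + noise: the exponent 0.8 encodes negative
  allometry (no published exponent exists; the value is config-exposed),
  the intercept is solved at run time by lognormal moment matching so the
  male GV mean hits its target, and the residual log-SD of 0.15 makes the
  implied GV coefficient of variation match the published 1320.86/5384.
* **Canal effects.** Each of the eight base measures (six linear
  dimensions, two angles) is generated in log space as a per-sex template
  mean plus configured effects of *centred* log GV and log weight (plus a
  male interaction) plus normal residual (SD 0.08, which reproduces the
  modest adjusted R² range seen in this kind of data). Female defaults
  take the published additive-model coefficient pattern (e.g. θ_a effect
  of log GV = −0.11); male defaults are modest main effects plus an
  interaction that qualitatively matches the male sign pattern — the true
  study effect sizes are unknowable, so these defaults claim realism of
  structure, not of value. Shape indices are **derived** as AP/ML of
  generated dimensions, never generated independently, so the ratio
  identity holds by construction; an effect on a shape index is implied
  by the difference of its parents' effects. Centring the predictors
  means the additive-model and interaction-model coefficients of interest
  equal the configured values exactly, which is what makes clean coverage
  checks possible.
* **Landmarks.** For each specimen a landmark configuration is built that
  reproduces the row's measurements exactly: MML, θ_a and θ_b fix the
  spine/S5 triangle through the law of sines (feasible iff
  θ_a + θ_b < 180°, otherwise an infeasible-geometry error), and the
  remaining landmarks are placed so each defined pair realises its
  distance. Template coordinates are plumbing with realistic magnitudes,
  not a claim about any real pelvis. A random rigid motion puts each
  specimen in its own scanner frame; observer noise is a constant
  per-observer offset vector plus per-landmark jitter (1 mm default),
  inflated to 5 mm on the ischial tuberosities to emulate the fuzzy
  outlet landmarks. Replicates within an observer re-digitise only the
  fuzzy landmarks, so replicate averaging is exercised exactly as
  intended.
* **Masks.** `simulate_mask_stack()` packs the exact pixel count for a
  target volume into square slices, so the volumetry round trip is exact
  to half a voxel.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: non-normal weight/GV tails,
covariance between canal measures beyond that induced by the shared
predictors, anatomically realistic landmark error fields (real
digitisation error is anisotropic and structured, not iid spherical),
secular, age or ancestry structure, and any segmentation error in the
masks. Parameter-recovery results certify the estimation machinery, not
the biology.

## Problem sizes and determinism

All stochastic checks fix seeds and use sizes chosen to make Monte-Carlo
error small relative to the tolerance being asserted: 100 random
configurations for the geometry oracles (tolerance 1e−9), 100 random
matrices for the ICC-vs-ANOVA oracle (1e−10), n = 2000 with 40 rater
draws for ICC consistency (tolerance 0.02 — at fixed k the realised
rater-effect variance does not average out within one matrix, so
consistency is checked on the mean across rater draws), 500 simulated
cohorts at the study sizes (44 male / 48 female) for confidence-interval
coverage (expected ≈ 95%, asserted ≥ 93%), and 2000 null cohorts for the
false-positive rate at α = 0.01. Every generator function sets its seed
from the config, so a fixed config yields bit-identical cohorts,
landmarks and reports; the pipeline writes a manifest with checksums of
all artifacts.

## Known limitations

* The angular statistics inherit the left-vertex definition of θ_b; on
  strongly asymmetric pelves the right-vertex analogue would differ, and
  no symmetrised variant is provided.
* Volumetry has no partial-volume correction; accuracy at coarse pixel
  spacing is first-order in the spacing.
* The inference stage is ordinary least squares: no measurement-error
  model propagates landmark or volumetry uncertainty into the
  coefficients, and no mixed-effects structure pools across responses.
* Relative weights are an approximate attribution; they are exact only in
  their R² conservation, not as causal shares.
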