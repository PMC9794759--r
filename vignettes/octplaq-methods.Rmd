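---
title: "Methods: IVOCT plaque morphometry and risk modelling with octplaq"
author: "octplaq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IVOCT plaque morphometry and risk modelling with octplaq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`octplaq` quantifies coronary plaque morphology on intravascular optical
coherence tomography (IVOCT) pullbacks represented in polar coordinates,
and models a binary lesion outcome (in-stent neoatherosclerosis) from
the resulting features. This vignette documents the models, the
parameter defaults and their rationale, the numerical conventions, and
what the synthetic data used in testing do and do not establish.

## Image model and conventions

A pullback is an ordered stack of polar frames: each row of a frame is
one A-line (angular sample), each column one radial sample. A-line 0
points at 12 o'clock with the angle increasing clockwise; radial pixel 0
sits at the catheter center. Physical calibration is carried by
`pixel_size_radial` (mm/pixel, default 0.005 = 5 µm — typical
frequency-domain IVOCT axial sampling) and `frame_pitch` (mm between
frames, default 0.2). On disk a pullback is a 16-bit multi-page TIFF
plus a JSON sidecar carrying the calibration and per-frame annotations
in 0-based (A-line, radial-pixel) indices; the sidecar's
`schema_version` is mandatory, and traced boundaries are stored under
their own `traces` key so planted ground truth is never overwritten.

Frame pitch deserves emphasis: lesion length and fibrous-cap (FC)
surface area scale exactly linearly with it, so it is an explicit
configuration value rather than a buried constant. The 0.2 mm default
corresponds to conventional frequency-domain pullback spacing; any
analysis of real data should set it from the acquisition protocol.

## The phantom generator

`generate_pullback()` renders the intensity stack implied by a
`phantom_config()`: a dark lumen (0.05), bright tissue (0.80) beyond
the lumen boundary, and for A-lines inside a planted cap a sigmoidal
bright-to-dark radial decay centered on the planted abluminal boundary,

$$ I(r) = I_d + (I_b - I_d)\,\bigl(1 + e^{(r - r_{ab})/w}\bigr)^{-1}, $$

with half-width $w$ = `decay_half_width` (default 4 pixels). This is the
image evidence the tracer is designed for: the FC abluminal boundary
presents as a gradual bright-to-dark transition rather than a sharp
edge. Calcium renders as a signal-poor region (intensity × 0.25) with
sharp borders; A-lines without a cap attenuate exponentially (length
constant 60 pixels). Additive Gaussian noise of configurable SD is the
only stochastic element, so a config + seed is bit-reproducible, and two
seeds share identical geometry while differing in noise.

Alongside the stack the generator returns the **analytic** 17-feature
vector of the planted geometry (circle areas, annular-sector cap areas
with exact integrals of the linear thickness profile, arc × pitch
surface areas). This vector is computed from the configuration in closed
form, independent of the image-processing path, and anchors the
oracle tests: extraction from a noiseless phantom must reproduce it
within 1% on lengths/areas and 1° on angles.

What the phantom deliberately does **not** emulate: OCT speckle
statistics, guide-wire shadows, catheter eccentricity, stent struts, and
post-stent neointima. Passing the phantom suite therefore establishes
geometric and statistical correctness of the measurement chain, not
robustness to real-image artifacts — segmentation of real pullbacks
still relies on upstream lumen/calcium annotations of adequate quality.

## Abluminal boundary tracing

`edge_cost()` smooths each A-line radially with a Gaussian kernel
(σ = 2 pixels by default) and takes the central-difference radial
derivative; the cost is this derivative min–max normalized to [0, 1] per
frame, so the minimum-cost radius on an A-line is where the intensity
falls fastest. A frame with no intensity variation yields a uniform cost
grid and a warning marker rather than an error.

`trace_abluminal()` finds the global minimum-cost path across the
angular window by dynamic programming with per-step transitions bounded
by `smoothness_cap` (default 2 pixels per A-line — about the wall
curvature expressible at 1° angular sampling), restricted to radii
strictly outside the lumen boundary plus one pixel. Conventions chosen
for determinism and clinical conservatism:

* cost ties break toward the smaller radius, i.e. toward the thinner —
  riskier — cap;
* the path is open over the window; for full-circumference windows a
  `wrap` mode pads the window cyclically before solving and discards the
  pads, an approximate periodic closure (exact periodic DP would cost a
  factor of the radial dimension);
* sub-pixel refinement fits a parabola through the cost at each integer
  path point (offsets clamped to ±0.5 pixels and rescaled, if necessary,
  so the smoothness cap still holds); it can be disabled.

Because the DP accumulates costs in the same left-to-right order as a
naive path sum, its optimum is comparable bit-for-bit with an exhaustive
enumeration oracle, which the test suite exercises on 200 random small
instances.

## The 17 lesion-level features

Per frame: lumen area by the shoelace rule on the closed contour
(per-A-line polar contours with positive radii are star-shaped, so
self-intersection cannot occur); lumen diameter as the area-equivalent
circle diameter $2\sqrt{A/\pi}$ (a minimum-caliper alternative is
available via `diameter_method = "caliper"`); perimeter as the summed
segment lengths. Angular extents of calcium and cap are measured at the
**lumen centroid** — not the catheter center — so they are invariant to
catheter position. Calcium thickness and depth are radial distances
(outer − inner, inner − lumen) per covered A-line; cap thickness is the
radial luminal→abluminal distance; cap cross-sectional area is the
polygon bounded by the two boundaries and the end radii (the annular
difference for 360° caps); the covered arc is the lumen contour length
inside the cap window.

Lesion aggregation: lesion length = frames × pitch; lumen features are
min/mean over all lesion frames; calcium and cap extrema are taken over
component-bearing frames only — a frame without calcium contributes
nothing, rather than a zero, which is why lesion-level *minimum* angles
are well above zero in realistic cohorts. For the paired extrema the
lesion maximum is the maximum of per-frame maxima and the lesion minimum
the minimum of per-frame minima. Lesions without a component carry
missing values into the cohort table, never zeros. Maximum calcium angle
uses the per-frame **sum** over disjoint deposits (the per-deposit
alternative would ignore multi-deposit frames).

The two lesion-integral cap features are

$$ S_{FC} = \sum_f \ell_f \,\Delta z, \qquad
   B_{FC} = \frac{\sum_f a_f \,\Delta z}{\sum_f p_f \,\Delta z}, $$

with $\ell_f$ the covered lumen arc, $a_f$ the cap cross-sectional area
and $p_f$ the lumen perimeter of frame $f$. $S_{FC}$ is the lumen
surface area covered by cap. $B_{FC}$ — cap volume normalized by lumen
surface area — has dimension mm at mm scale and is numerically small
(≈ 0.1 for a 100 µm cap); burden values quoted in the literature for
this kind of measure are often of order 10²–10³ with no stated scale, so
the package emits the literal ratio and attaches a ×1000 convenience
value (`fc_burden_x1000`) in the extraction output rather than guessing
a convention. The cohort generator parameterizes the burden feature
directly on the large scale, so the statistical chain is unaffected by
this ambiguity.

## The cohort generator

`generate_cohort()` draws lesion rows from per-feature Gaussian moments
specified separately for the event and control groups, coupled through a
Gaussian copula: a target within-block Spearman ρ is mapped to the
latent Pearson correlation $2\sin(\pi\rho/6)$, so rank correlations are
exact in distribution rather than approximated by arithmetic
duplication. Blocks may carry ±1 signs per member (one anti-correlated
member, e.g. minimum cap thickness against cap bulk). Infeasible
(non-PSD) structures are rejected naming the offending block.

Physical features cannot be negative, so negative draws are **clipped to
zero** rather than resampled — resampling would break the one-to-one map
from seed to output. The clipped fraction is reported per feature and
overall (attribute `truncation`); under the reference moments it is
about 6%, dominated by features whose mean sits within ~1 SD of zero
(minimum calcium depth, minimum cap thickness, cap surface area and
burden in the control group). Consumers should note that clipping
shifts a clipped feature's realized group mean to the truncated-normal
mean; the tests check the bookkeeping against that analytic value.

Two outcome models are supported: `"group-labels"` (features conditional
on the label, the two-group design above) and `"logistic"` (features
from the control moments for all rows, labels drawn from a stated
logistic link) — the latter is what parameter-recovery and
coverage simulations need.

The demo configuration (`demo_cohort_config()`) plants six blocks — four
tightly collinear groups at ρ = 0.95 (lumen; calcium angles; calcium
thickness/depth; cap angles), one cap-bulk group at ρ = 0.85 (just below
the pruning threshold), and lesion length as a singleton — with
fibrous-cap surface area as the only feature whose moments differ
between groups. Its analysis outcome is therefore known by
construction: clustering at k = 6 recovers the blocks, pruning at
|ρ| > 0.9 removes exactly the 8 within-block duplicates, and only the
planted feature should survive to multivariate significance.

## Statistical chain

* **Group comparison.** Classical pooled-variance Student t-tests,
  two-sided, missingness handled per feature; Welch's correction is a
  flag (`welch = TRUE`) rather than the default because the pooled test
  is the stated convention of this analysis style.
* **Collinearity.** Spearman ρ on pairwise-complete observations with
  average ranks; the heatmap quantity is ρ². Hierarchical clustering
  uses the squared Euclidean distance between rows of the ρ² matrix;
  linkage is complete by default (compact, well-separated blocks;
  `average` and `ward.D2` are available) and the tree is cut at a
  configurable k (default 6). The **operative** elimination rule is the
  |ρ| > 0.9 threshold — of every such pair the feature with the larger
  univariate p is eliminated, iterated to a fixed point by visiting
  features in ascending-p order (ties by the canonical feature order) —
  while the dendrogram is the descriptive view; both are reported. The
  procedure is idempotent and never leaves a retained pair above the
  threshold.
* **Logistic regression.** Plain maximum likelihood via IRLS
  (convergence 10⁻¹⁰, ≤ 100 iterations); Wald odds-ratio intervals
  $e^{\hat\beta \pm z_{.975}\,SE}$. Zero-variance predictors are dropped
  with a warning; remaining rank deficiency is an error naming the
  aliased columns. Quasi-separation — a standardized coefficient
  drifting beyond 15 — is flagged with a warning, which matters at 19
  events: the multivariate model after the univariate screen
  (inclusion at p < 0.05) runs on few events per variable, and the
  instability is surfaced rather than hidden. A Firth bias-reduced fit
  (adjusted-score IRLS) is available by flag for separated or
  few-events settings. Multivariate fits use complete cases across the
  selected predictors; because calcium-free lesions carry missing
  calcium features, selecting a calcium feature shrinks the multivariate
  sample, and the fitted n is reported. No multiple-testing correction
  is applied by default, matching the analysis style being reproduced.
* **ROC.** The AUC is the tie-corrected Mann–Whitney rank statistic
  (higher score ⇒ positive class); its CI comes from DeLong's method by
  default or a seeded stratified bootstrap. The operating point
  maximizes sensitivity + specificity over midpoint thresholds, ties
  broken toward the higher specificity, then the higher threshold. A
  constant score returns AUC 0.5 with a degenerate-score warning.

## Determinism and the pipeline

`run_pipeline()` executes simulate → extract → select → analyze and
writes every intermediate artifact in a re-readable format; all writers
are atomic. One global seed spawns fixed per-stage substreams
(`stage_seed`), so a stage re-run in isolation reproduces its output and
two runs of the same configuration produce byte-identical report JSON
(numbers serialized at fixed precision; the provenance block records
seed, configuration MD5 and package version, and deliberately no
timestamp). Stage errors abort with the stage name and the offending
input.

## Problem sizes used by the test suite

The suite runs phantoms of up to 12 frames at 360 × 500 pixels;
exhaustive path enumeration on 200 instances up to 8 A-lines × 8 radii;
100 random small logistic datasets against a direct likelihood
optimizer; 2,000 null replicates (n = 200) for the type-I calibration of
the univariate screen; 200 replicates at n = 2,000 for Wald coverage of
a planted odds ratio of 1.38; and 10⁴-per-group cohorts for the
binormal AUC check, Φ(19.74/√(7.76² + 7.43²)) ≈ 0.967. These sizes were
chosen as the smallest at which the Monte-Carlo tolerances (binomial 3σ
bands, ±0.01 on the AUC) are meaningful.

## Known limitations

* Lumen and calcium boundaries are annotation inputs; the package does
  not segment them from images.
* The wrap-around trace is an approximate periodic closure.
* Wald inference at 19 events is fragile near separation; the Firth
  option mitigates but the default reproduces the plain-MLE convention.
* The phantom's intensity physics is schematic (no speckle, shadows, or
  struts), so image-level results on real pullbacks depend on upstream
  data quality in ways the synthetic suite cannot certify.
* Macrophage, microchannel and cholesterol-crystal features are out of
  scope, as is any automatic detection of the lesion frame range.
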