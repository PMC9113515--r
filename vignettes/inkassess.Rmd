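---
title: "Methods: digital pen features and automatic scoring of neurocognitive assessments"
author: "inkassess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital pen features and automatic scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inkassess)
```

## The data model

Digital ink is an ordered list of strokes; a stroke is one pen-down to
pen-up episode, an ordered run of points $(t, x, y, p)$. Canonical units
are milliseconds for time, millimetres for coordinates with $x$ to the
right and $y$ downward (the scan convention, so clockwise on paper is
clockwise in data), and pressure normalized to $[0, 1]$. Digitizing pens
differ in native units; readers accept the data as stored and unit
conversion is left to ingest, a deliberate choice because no universal pen
coordinate unit exists. A missing force channel defaults to pressure 0.5
with a warning rather than rejection, since several digitizers omit force.

Two serializations are supported — W3C-style InkML (one `<trace>` per
stroke, channel order X Y T F) and a JSON-lines dialect (one sample per
line) — and both round-trip doubles exactly (17 significant digits), so a
written cohort is a faithful archive. The only preprocessing applied
anywhere is translation to the coordinate origin
($\min x = 0$, $\min y = 0$); no scaling, resampling or smoothing touches
the stored trajectory, to avoid distorting the writer's kinematics.
`translate_to_origin()` preserves the full inter-point distance matrix and
is idempotent. Completion time is defined as the last recorded timestamp
minus the first, in seconds.

Noise strokes (stray notes, scribble) are a curation problem, not an
inference problem: nothing in the package tries to detect them, and a
sample is used exactly as given.

## The feature bank

`feature_registry()` fixes 176 features in five provenance-tagged
families: 13 stroke-appearance features (initial angle sine/cosine,
bounding-box diagonal, start-end vector, path length, total signed /
absolute / squared turning angle, maximum squared speed, duration), 89
trajectory features (velocity, acceleration and jerk statistics, pressure
statistics, curvature and perpendicularity sums, convex-hull and
bounding-box geometry, direction and curvature histograms, and meta
features such as self-crossings, straight-line runs, connected strokes and
pen-up behaviour), 49 heterogeneous baseline features (box-normalized
first/last point attributes, a $3\times3$ zoning histogram and an 8-bin
direction histogram over a 64-point arc-length resampling,
scale-normalized central moments, compactness, eccentricity,
rectangularity, circular variance), 14 mode-detection shape descriptors,
and 11 features from the cognitive-assessment literature.

Design choices worth knowing:

* **Families are not deduplicated.** Several quantities (path length, hull
  properties, stroke counts) legitimately appear in more than one family;
  each family keeps its own namespaced copy so the family cardinalities
  13 + 89 + 49 + 14 + 11 = 176 are part of the contract. The registry
  order — family by family, source grouping within family — is fixed by
  this package and every feature table follows it.
* **Velocity is a central finite difference on raw timestamps**, one-sided
  at stroke endpoints, with no smoothing. This makes kinematic features
  checkable against an independent finite-difference oracle to $10^{-9}$
  relative error, which the test suite does on a thousand random strokes.
* **Lifts and pauses.** Every pen-up interval between consecutive strokes
  is a lift; a pause is a lift of at least 200 ms (configurable). The
  200 ms default is a common convention in handwriting analysis; nothing
  downstream is sensitive to it except the three pause features
  themselves.
* **Degenerate input never yields NaN/Inf.** Angle-type features of
  single-point or zero-extent strokes fall back to 0, ratio features with
  zero denominators fall back to 0 (the sketch/pause ratio of a
  single-stroke sample is such a guard), and a final sanitizer enforces
  finiteness. Rows produced entirely from fallbacks are kept in feature
  tables — only samples with no ink at all are rejected — mirroring the
  practice of discarding only empty sketches.
* **Stroke-level evaluation** treats each stroke as a one-stroke sketch,
  so sketch-oriented features (lift statistics, stroke counts) are defined
  everywhere but carry no information at stroke granularity; that loss is
  part of what the granularity comparison measures.
* **Self-crossings** are counted on the 64-point resampled path rather
  than the raw trajectory; this bounds the quadratic segment-intersection
  test and makes the count robust to sampling density.

## The scorers

**Clock (CDIS).** The scorer consumes a semantic stroke segmentation
(classes: circle, digit 1–12, hour hand, minute hand, centre point, helper
line, other). Ground-truth segmentations pass through verbatim; a
geometric heuristic (largest nearly-closed contour → circle, strokes
anchored near the centre → hands, rim clusters → digits by angular sector)
covers unsegmented input, with digit *identity* taken from angular
position — full digit recognition is out of scope. Twenty binary item
predicates over this segmentation are summed to the 0–20 total. Only the
scheme's overall shape is published item-by-item, so the predicates are a
declarative reconstruction with explicit tolerances: digit and hand angles
within 15°, circle closure gap at most 10% of the perimeter, radial
coefficient of variation at most 0.15 for roundness, hands anchored within
0.15 r of the centre. All tolerances are arguments of `cdis_params()`.

**Trail.** The 25-node layout of the published instrument is under
copyright and not deposited, so `tmt_template()` builds a synthetic
serpentine A4 layout with deterministic jitter (part B alternates
1, A, 2, B, …, 13). A node is hit iff any pen point falls within its
radius (5 mm default — the printed circle is the natural capture region);
node visits are the run-length encoding of per-point nearest-hit nodes in
time order, a required connection $(i, i{+}1)$ is made iff $i{+}1$ is
visited immediately after $i$, and everything else becomes a transparent
error note. Completion time — the clinical score — is plain timestamp
arithmetic.

**Complex figure.** The 18 sub-figures are scored independently: 0 when
absent, 2 when drawn correctly (shape similarity ≥ 0.85 after centroid
alignment, where similarity is $1 - \text{chamfer}/(0.25\,s)$ with $s$ the
reference sub-figure diagonal) *and* placed correctly (centroid within
10 mm), 1 otherwise. The published scheme does not print the criteria
separating 1 from 2; "present but failing shape or placement" is this
package's reconstruction, with both thresholds configurable. The reference
geometry is a synthetic schematic of the standard figure.

**Labels.** `label_sample()` applies the screening thresholds: CDIS ≤ 18,
ROCF ≤ 30 (all three administrations), TMT-A strictly over 60 s, TMT-B
strictly over 120 s. The rules are monotone by construction: lowering a
score or raising a time can never flip suspicious to healthy.

## The synthetic cohort generator

The generator exists so every scorer and the benchmark are testable
without clinical data; its defaults are the package's fixed study
conditions, not tuning knobs. A behaviour profile holds mean pen-down
velocity (mm/s), velocity coefficient of variation, mean pressure, pause
rate (per minute), mean pause duration (ms), tremor amplitude (mm) and an
omission probability. The defaults — healthy: 25 mm/s, CV 0.2, pressure
0.60, 2 pauses/min of 400 ms, 0.15 mm tremor, no omissions; impaired:
12 mm/s, CV 0.35, pressure 0.45, 6 pauses/min of 1500 ms, 0.5 mm tremor,
omission probability 0.15 — realize the qualitative directions reported
for cognitively impaired elderly writers (higher temporal measures, lower
pressure, less regular movement). No quantitative effect sizes for
impaired pen kinematics are deposited anywhere, so the magnitudes are this
package's own calibration, chosen once to produce clinically plausible
completion times (a healthy clock in ~15–20 s, an impaired trail around
80–140 s) and left alone.

Numerical choices: sampling is fixed at 100 Hz (a typical digitizer
class); per-stroke speeds are truncated normals (floor at 15% of the
mean); tremor is modelled as a 4–8 Hz oscillation with random phase
rather than white noise — independent per-sample noise would inflate path
length and make tremulous writers look *fast*, inverting the very
kinematic signature the features measure; pauses are Poisson-allocated to
pen lifts (clock, figure) or node arrivals (trail); part B gets a three
times longer per-node decision dwell than part A, standing in for
set-shifting cost. Cohort labels are obtained by scoring the generated ink
and applying the labeling rules, so an impaired subject who happens to
draw a complete clock is labeled healthy — the class boundary overlaps
like real screening data. A figure draw whose sub-figures are all omitted
is rejected as empty (cohort generation redraws it).

What the generator does **not** emulate: individual handwriting styles,
digit glyph shapes (digits are schematic marks; identity lives in the
ground truth), diagnosis subtypes, hesitation micro-dynamics within
strokes, or device artefacts. Green tests on synthetic cohorts therefore
show that the pipeline recovers *engineered* impairment signatures, not
that any classifier reaches clinical accuracy.

## The benchmark

`run_grid()` evaluates the ten-classifier roster on the six tables from
{sketch, stroke} × {all 176, the 165 literature features, the 11 cognitive
features}: 60 runs. Hyperparameters are pinned in `make_classifier()`:
SVMs at $C = 1.5$ (iteration cap 10,000 recorded; libsvm runs to its own
convergence), logistic regression at $C = 8.0$ — realized as
ridge-penalized likelihood with $\lambda = 1/(C n)$, the solver name
recorded as metadata — 7-nearest neighbours, Gaussian naive Bayes with a
$10^{-9}$ variance floor, trees at documented defaults (100 trees for
forest and boosting, 50 AdaBoost rounds at learning rate 0.5), and a
single-hidden-layer MLP with 1,000 tanh units, $\alpha = 1$, learning rate
0.001, Adam. The width is read as 1,000 *units*, not 1,000 layers, the
only trainable interpretation at these sample sizes; it is a config field
like everything else. AdaBoost (SAMME over stumps) and the Adam MLP are
implemented in the package; the rest call the standard R libraries.

Evaluation is stratified 10-fold cross-validation. Standardization is
computed on each training fold only — the feature tables are never scaled
globally, which would leak test statistics into training; a noise-table
canary in the test suite checks that cross-validated performance on pure
noise stays at the majority baseline. Accuracy and macro-averaged
precision/recall are averaged over folds with equal weights; F1 is the
harmonic mean of the averaged precision and recall; ROC curves and AUC
come from the fold-concatenated decision scores (pooling is the
lower-variance choice at these test-fold sizes, and is recorded here
because averaged-fold AUC is a defensible alternative). Linear-SVM
interpretation weights are the fold-averaged absolute primal weights.
t-SNE (exact, $O(n^2)$, implemented in the package) embeds feature tables
at the standard visualisation settings — 2 components, perplexity 30,
early exaggeration 12, learning rate 200, 1,000 iterations — shrinking the
perplexity with a warning when a table is too small for it.

## Problem sizes and determinism

The test suite exercises the statistical claims at sizes chosen to keep a
full run comfortably on one CPU: the 60-run grid is verified on a
60-sample trail cohort (trails are single strokes, so stroke-granularity
tables stay at 60 rows while still exercising both granularities); the
impairment-direction and granularity-ordering checks run on a 200-subject
clock cohort with the 11 cognitive features (one-sided rank tests at
$p < 0.01$; whole-sketch mean CV accuracy above single-stroke mean CV
accuracy across the roster); the oracle-equivalence suites use 1,000
random strokes of at most 20 points and hulls of at most 15 points. Every
stage — generation, extraction, CV, embedding — is deterministic given its
seed, and the acceptance script reruns the labeling-boundary enumerations
and the perfect-figure scoring from scratch on each invocation.

## Known limitations

The CDIS item predicates and the ROCF 1-vs-2 criteria are geometric
reconstructions with explicit tolerances, not transcriptions of the
clinical manuals; the trail template is a synthetic layout, so absolute
completion times depend on its ~900 mm path length; digit and letter
identity in heuristic segmentations comes from position alone; and
benchmark numbers on synthetic cohorts characterize the pipeline, not
clinical performance. All thresholds that embody these reconstructions are
exposed as function arguments so that a user with instrument-faithful
templates or calibrated tolerances can substitute them.
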