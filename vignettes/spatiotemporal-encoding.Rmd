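---
title: "Spatiotemporal encoding of scanpaths and the expertise benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal encoding of scanpaths and the expertise benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scanbin)
```

## The problem

When radiologists inspect a chest x-ray, their gaze traces an ordered
sequence of fixations — a scanpath. Expert and trainee readers search
differently: experienced readers tend to sweep the image systematically and
allocate attention broadly, while less experienced readers dwell on a few
regions where they suspect abnormalities and return to them repeatedly.
scanbin asks whether that difference is machine-measurable: can a classifier
fed only gaze data tell the two expertise levels apart, and does a
spatiotemporal *encoding* of the scanpath beat the handful of summary
statistics ("traditional" gaze features) that the eye-tracking literature
has converged on?

## The encoding

For one trial with fixation coordinates $F \in \mathbb{R}^{n \times 2}$, the
encoder discretizes both space and time:

1. split the ordered fixations into $t$ temporal groups;
2. tile the display with an $x \times y$ Cartesian grid and assign each
   fixation to the grid cell with the nearest centroid;
3. count fixations per cell per temporal group, giving $t$ count grids;
4. flatten and concatenate the grids into a single vector
   $V \in \mathbb{N}^{1 \times (x \cdot y \cdot t)}$.

The vector length depends only on the configuration, never on trial length:
longer trials produce larger counts, shorter ones sparser vectors, which is
exactly what lets trials of different durations share one fixed-width
feature matrix.

Choices the definition above leaves open are fixed as follows, and all of
them are exercised by the test suite:

* **Temporal splitting.** Two modes exist because the natural-language
  description of the method (equal spans of *time*) and its pseudocode
  (equal *counts* of fixations) disagree. `binning = "time"` (default)
  divides the span from the first onset to the last onset plus last duration
  into $t$ equal half-open intervals $[a, b)$, the final interval closed, and
  assigns by onset; a zero-length span degenerates to the first group.
  `binning = "count"` splits the sequence into groups whose sizes differ by
  at most one, larger groups first ($n = qt + r$ gives $r$ leading groups of
  size $q + 1$). Time mode is the default because it is the variant that
  actually transports trial duration into the feature vector.
* **Cell assignment.** Nearest centroid under Euclidean distance. A point on
  a shared cell boundary is exactly equidistant between centroids; the tie
  goes to the lowest row-major index. The implementation uses the
  closed-form `clamp(ceiling(v / w) - 1, 0, g - 1)` per axis, which the
  suite verifies against an explicit argmin-over-all-centroids oracle on an
  exhaustive half-pixel sweep plus fuzzed points.
* **Out-of-display fixations.** `oob = "clamp"` (default) lets the argmin
  assign them to the nearest edge cell, so the vector total always equals
  the fixation count — a conservation law the tests check on random trials.
  `oob = "drop"` discards them first, for pipelines that prefer filtering.
* **Flatten order.** Temporal-major, row-major within each grid, fixed
  bit-exactly so that feature indices are portable across runs and tools
  (`b{bin}_r{row}_c{col}` column names).
* **Grid extent.** The grid tiles the full display rectangle, not the
  stimulus content. Data recorded relative to an image must be transformed
  to display coordinates before ingestion (origin top-left, x rightward,
  y downward, pixels; time in seconds).

## The traditional baseline

Five per-trial summary features serve as the comparison baseline: total scan
time, fixation count, regressive fixation count, total saccade length, and
coverage. Features that require knowing where the abnormality actually is
(dwell time or fixation count on the lesion, time to first hit) are
excluded by design — they need manual ground-truthing of every image, which
is precisely what limits their deployment.

Two of the five are underdetermined in the literature and are pinned down
here:

* **Regressive fixations** count returns to a previously *visited location*
  after the gaze has left it. "Location" is operationalized as a cell of a
  coarse grid (default 5×5): a fixation is regressive when its cell was
  visited before and at least one intervening fixation fell elsewhere;
  consecutive same-cell fixations are dwell, not regression. This keeps the
  count deterministic and bounded by `fixation_count - 1`.
* **Coverage** is the fraction of *salient* display area within a disc of
  the gaze. Discs have radius 2% of the display diagonal by default,
  approximating the ~1 degree accuracy of remote eye trackers. The salient
  mask is everything that is not peripheral black background; with a
  stimulus image it is computed by thresholding (default 0.05), morphological
  closing, and taking the bounding box of the largest connected component —
  so dark anatomy *inside* the radiograph stays salient — and without an
  image the whole display counts as salient.
* **Saccade length** is the spatial Euclidean path length between
  consecutive fixations. One strand of the literature glosses it as "time
  between fixations"; the spatial reading is the standard one and is what is
  implemented.

## The synthetic generator

The human datasets the method was developed on are not publicly deposited,
so the package ships a generator that emulates their *design* and the
*qualitative* behavioural contrast, not their numbers. Two archetypes are
parameterized (`archetypes(separation)`):

* **faculty** — high probability (0.60 at full separation) of following a
  systematic serpentine sweep across the display, near-uniform attention
  over six dispersed anchor regions, broad cluster spread, rare revisits;
* **trainee** — low sweep probability (0.08), attention concentrated on two
  tight suspicion regions, frequent revisits (0.55).

`separation` interpolates every parameter linearly between the common
midpoint (separation 0: the classes are identical, so any classifier must
sit at chance) and the full contrast (separation 1). The default, 0.8, is
calibrated so that the encoded-feature pipeline on the default design
reaches cross-validated AUC at or above 0.9 — the regime the method is
meant to demonstrate. Fixation counts are negative-binomial (mean 40,
dispersion 12, floored at 1), durations Gaussian (0.30 ± 0.08 s, floored at
20 ms), onsets cumulative, and coordinates receive 6 px isotropic jitter
before clamping into the display.

Two presets reproduce the study designs: `eyelink_like` (1 faculty + 1
trainee, 55 trials each → 110 trials, pre-filtered fixations) and
`tobii_like` (4 + 4 participants, 27 trials each → 216 trials, raw gaze
ingested as fixations: four times as many samples per trial, each lasting
one 30 Hz inter-sample interval, with four times the jitter). Participant
identity carries no random effect of its own: with one participant per class
in the eyelink-like design, any idiosyncratic participant signature would be
indistinguishable from a class signal and would lift the zero-separation
control above chance. Consequently the generator models class behaviour
only — which also means passing benchmarks here demonstrate the pipeline's
mechanics and discriminative headroom, not that human experts are this
separable. Real scanpaths add image-conditioned saliency, main-sequence
saccade dynamics, fatigue and calibration drift, none of which are
simulated.

Reproducibility: each trial draws from its own substream seeded by the
dataset seed and a trial counter, so datasets are bit-identical across runs
and machines for a fixed configuration.

## The benchmark protocol

`run_sweep()` reproduces the evaluation protocol at configurable scale:

* **Cross-validation.** Stratified folds in which each test set holds a
  fixed number of trials per class (default 10 folds × 5 per class). With
  110 trials this consumes 100 distinct test trials; the arithmetic does not
  tile 110 evenly, so the 10 leftover trials legitimately appear in every
  training set and no test set — enforced disjointness, documented rather
  than hidden. Folds are regenerated for every seed in `seeds`, and the seed
  is part of each record's key.
* **Configuration sweep.** Full-factorial over grid sizes (default
  {5, 7, 10, 15}) and temporal groups ({3, 5, 10, 20}) for the encoded data
  type — up to 15·15·20 = 4500 features — crossed with the traditional
  baseline, the feature-extraction variants and the classifier roster.
* **Dimensionality reduction.** PCA and kernel PCA, either to a fixed
  dimension (2 in the study design) or to a fixed explained-variance target
  (50 / 90 / 99%; kernel-space eigenvalue fractions for KPCA). The
  projection is always fitted on the training split only — the test rows
  cannot influence it — and the KPCA bandwidth uses the median
  pairwise-distance heuristic on the training split. KPCA projections are
  rescaled so that a linear kernel reproduces PCA scores exactly (up to
  sign), which the suite asserts.
* **Classifiers.** Gaussian process (Laplace approximation, RBF kernel; the
  bandwidth is the median heuristic scaled by a tuned factor, since the
  underlying implementation does not expose marginal-likelihood
  optimization), ridge-penalized logistic regression, k-nearest neighbours,
  and gradient-boosted trees. Hyperparameters are tuned by inner stratified
  cross-validation on the training split maximizing balanced accuracy, then
  the model is refit on the whole training split and scored once on the
  untouched test split.
* **Metrics.** AUC via the rank statistic with ties counted ½ (verified
  against a brute-force all-pairs oracle), F1, accuracy, sensitivity and
  specificity, with *trainee* as the positive class — specificity is the
  recall of the experienced class. Aggregation at any level of granularity
  always averages the lowest-level records directly, never re-averages
  intermediate means.
* **Scaling.** The five traditional features live on wildly different
  scales and are standardized per training fold by default; encoded count
  vectors are used raw by default, with a switch.

`select_best_config()` mirrors the study's per-classifier model selection
(argmax of mean AUC, ties to the simpler configuration: smaller grid, fewer
temporal groups, no reduction first), and `compare_gain()` reports
encoded-minus-traditional means in percentage points per device and metric.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run a reduced sweep — grids
{5, 10} × temporal groups {3, 10}, GP and logistic regression, 3 seeds for
the separated condition and 5 for the zero-separation control — which keeps
a full run in minutes while still crossing every axis of the design. The
full-factorial defaults remain available through `sweep_config()`.

Degenerate inputs are defined, not errors: an empty trial encodes to the
all-zero vector of full length; a zero-length temporal span puts all
fixations in the first group; a constant feature column survives
standardization (sd treated as 1); an all-removed trial filters to an empty
trial with a warning. `class::knn` breaks exact distance ties randomly, so
the harness seeds it per call to keep records reproducible.

## Limitations

* The generator's distributional forms (Gaussian mixtures, serpentine
  sweep, negative-binomial counts) are the package's own modelling choices;
  no quantitative scan statistics of the original participants are
  available to match.
* The AlexNet-style deep classifier of the original comparison is out of
  scope; any model exposing the fit/predict-probability contract can be
  added to the roster, but none is shipped.
* Real-data AUCs cannot be reproduced without the non-deposited recordings;
  the benchmark demonstrates the directional finding (encoded ≥ traditional,
  chance at zero separation) on synthetic data only.
* Fixation detection from raw samples (I-VT/I-DT), blink handling and
  native eye-tracker formats are out of scope; data enter as delimited
  fixation tables.
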