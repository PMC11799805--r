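# scanbin

Spatiotemporal binning and expertise classification of eye-tracking
scanpaths.

## What it is for

Radiologists' visual search patterns differ with experience: experts tend to
sweep an image systematically while trainees dwell on and revisit a few
suspicious regions. scanbin turns each recorded trial — an ordered sequence
of gaze fixations on a displayed image — into machine-learnable features and
benchmarks how well those features discriminate the two expertise levels.

Its core is a discretized spatiotemporal encoding. For a trial with
fixation coordinates $F \in \mathbb{R}^{n\times 2}$, the fixations are split
into $t$ ordered temporal groups; within each group they are counted over an
$x \times y$ grid tiling the display, each fixation assigned to the cell
with the nearest centroid ($C^{*} = \arg\min_C \lVert C - f_j \rVert$); the
$t$ count grids are flattened and concatenated into one vector
$V \in \mathbb{N}^{1 \times (x \cdot y \cdot t)}$. The length depends only
on $(x, y, t)$ — never on trial duration — so trials of any length share a
fixed-width feature matrix, with longer trials showing larger counts.

The package provides, end to end:

* a fixation data model with CSV readers/writers, validation and artifact
  filtering (`read_fixation_table()`, `filter_artifacts()`,
  `validate_dataset()`);
* the encoder (`encode_trial()`, `encode_dataset()`, `encoding_config()`);
* the five classic "traditional" per-trial gaze features used as baseline —
  total scan time, fixation count, regressive fixation count, total saccade
  length, coverage of the salient (non-background) image area
  (`extract_traditional()`);
* a two-class synthetic scanpath generator with `eyelink_like` (2
  participants × 55 trials, filtered fixations) and `tobii_like`
  (8 participants × 27 trials, raw-gaze-like) presets
  (`simulate_dataset()`);
* a benchmarking harness: stratified cross-validation with fixed per-class
  hold-outs, a full-factorial sweep over grid sizes and temporal groups,
  optional PCA/kernel-PCA reduction, Gaussian-process / logistic-regression /
  KNN / XGBoost classifiers tuned on balanced accuracy, and hierarchical
  metric aggregation (`run_sweep()`, `aggregate_records()`,
  `select_best_config()`, `compare_gain()`).

## Worked example

```r
library(scanbin)

ds <- simulate_dataset(simulation_config("eyelink_like", seed = 1))
ds
#> <gaze_dataset> device=eyelink_like, 110 trials (55 faculty / 55 trainee)

tr <- ds$trials[[1]]
tr
#> <gaze_trial F1_t1> participant F1 (faculty), 50 fixations, 1920x1080 px

v <- encode_trial(tr, encoding_config(grid_x = 3, t = 3))
v
#> <encoded_vector> length 27 (3x3 grid, t=3), total count 50
matrix(v$counts[1:9], 3, 3, byrow = TRUE)  # first temporal group's grid
#>      [,1] [,2] [,3]
#> [1,]    2    4    3
#> [2,]    0    1    1
#> [3,]    0    4    2
```

The 27-entry vector holds three 3×3 count grids, one per temporal third of
the trial; the first third above shows this simulated faculty trial already
spreading across the upper display. The total count (50) equals the trial's
fixation count — clamping out-of-display fixations to edge cells conserves
mass.

A miniature benchmark comparing encoded against traditional features:

```r
rec <- run_sweep(ds, sweep_config(grid_sizes = 5, temporal_groups = 3,
                                  classifiers = "lr", seeds = 1))
summary(rec)
#> Mean metrics by classifier, data type and feature extraction:
#>   classifier   data_type fe_method auc   f1 accuracy sensitivity specificity
#> 1         lr     encoded      none   1 1.00     1.00        1.00        1.00
#> 2         lr traditional      none   1 0.96     0.96        0.96        0.96

compare_gain(rec)
#>         device      metric encoded_mean traditional_mean gain_points
#> 1 eyelink_like         auc            1         1.000000    0.000000
#> 2 eyelink_like          f1            1         0.959596    4.040404
#> 3 eyelink_like    accuracy            1         0.960000    4.000000
#> 4 eyelink_like sensitivity            1         0.960000    4.000000
#> 5 eyelink_like specificity            1         0.960000    4.000000
```

Each row of `rec` is one cross-validation fold of one configuration; the
gain table reports encoded-minus-traditional means in percentage points. At
the default class separation (0.8) the encoded features separate the
synthetic classes essentially perfectly, while the traditional baseline
trails on the thresholded metrics; at `separation = 0` both drop to chance.

A shell entry point wrapping the same functions is installed with the
package (`system.file("cli", "scanbin.R", package = "scanbin")`) with
subcommands `simulate`, `encode`, `features`, `benchmark` and `render`.

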