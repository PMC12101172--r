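---
title: "Benchmarking drift correction with ground-truth synthetic reading trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking drift correction with ground-truth synthetic reading trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftlab)
```

## The problem

Eye trackers report gaze positions with a systematic error — drift — that
grows with calibration decay, head movement and pupil-size changes. In
reading research the damaging consequence is vertical: a fixation recorded
between two text lines, or on the wrong line entirely, corrupts every
word-level measure computed from it. Correction re-assigns each fixation
to a text line. Because manual correction is usually treated as the gold
standard, the accuracy of *any* corrector is hard to measure objectively:
the evaluation data are themselves a human judgment call.

`driftlab` takes the synthetic route: generate reading trials whose line
membership is known by construction, distort them with parametric drift
models, correct them, and count how many fixations return to their true
line. The same machinery quantifies *agreement* among several human
correctors on real data via per-fixation agreement and ICC(3,1).

## Coordinate conventions

All positions are in pixels with the origin at the top-left and y growing
downward. Line indices are 0-based everywhere, including CSV files. A text
layout is a list of word rectangles (AOIs) in reading order; `line_ys[k]`
is the y-coordinate shared by all AOIs of line `k` (their top edge), and
word centers are rectangle centers. Durations are milliseconds, carried as
doubles because the generator's duration formula is non-integer.

## The synthetic trial generator

The generator walks the AOIs in reading order and emits one fixation per
non-skipped word:

* **Landing site**: `x = aoi_x + width/3 + jitter`, `y = aoi_y + height/2
  + jitter` — one third into the word, mirroring the classic finding that
  readers land slightly left of the word center (the optimal viewing
  position), and vertically centered on the line.
* **Jitter** is Gaussian and independent per axis, default SD 2 px on both
  axes. The value is deliberately small relative to typical line spacing
  (40–80 px) so that an undistorted trial is perfectly recoverable; it
  exists to avoid the degenerate situation where all within-line y-values
  are bit-identical.
* **Duration** is `100 + (width/15)·40` ms, linear in word width — a
  960 px-per-second reading-speed surrogate that produces realistic
  260 ms fixations on a 60 px word. We read the width term as `width/15`
  (quarters of a 60 px word) because it is the only reading under which
  durations are proportional to word width and land in the plausible
  150–500 ms range.
* **Skipping** (optional, on in the benchmark): a word of `n` characters
  is skipped with probability `clamp(skip_base − skip_decay·(n−1), 0,
  skip_base)`, defaults `skip_base = 0.5`, `skip_decay = 0.08` — a 2-char
  word is skipped 42% of the time, a 10-char word never. Word length
  falls back to `width / char_width` (default 10 px/char) when the layout
  has no tokens. The first word of a line is never skipped, so every line
  retains at least one fixation — several correctors (cluster, merge,
  segment) implicitly assume non-empty lines.
* **Regressions**: every walk position after the third is independently a
  regression origin with probability `regression_probability`; if the
  draw selects none and the probability is positive, one origin is added
  at random, so regression trials always contain a regression. At an
  origin the walk jumps back to a uniformly drawn earlier word — on a
  *different* line (between-line variant) or the *same* line (within-line
  variant) — and re-reads forward from there. Target drawing retries up
  to ten times; if chance never produces a valid target but one exists,
  the generator falls back to a uniform draw among the valid targets
  (this keeps the "at least one regression" guarantee hard rather than
  probabilistic). Regression origins are consumed once, so a re-read
  cannot re-trigger its own regression and the walk always terminates.

Ground-truth line labels are recorded at generation time, not inferred
afterwards — after distortion the geometric line membership is exactly
what a corrector must reconstruct.

### What the generator does and does not emulate

It reproduces the features that matter for line assignment: multi-line
structure, optimal-viewing-position landing sites, word skipping,
re-reading after regressions, and duration/word-length coupling. It does
**not** model saccade trajectories, blinks, microsaccades, fatigue-related
temporal drift, or duration effects beyond word width. Passing benchmarks
here therefore demonstrate robustness to *geometric* drift patterns, not
to every artifact of real recordings; real-data agreement analyses
(`per_fixation_agreement`, `icc3`, `agreement_study`) are the complement
for that.

## Distortion models

Four parametric models, all order-, count- and duration-preserving:

| kind | transform | emulates |
|------|-----------|----------|
| noise | `y' = y + N(0, ynoise)` | uncorrelated vertical measurement error |
| slope | `y' = y + (x − x_first)/100 · f` | one-sided calibration error growing across the screen |
| shift | `y' = y + \|y − y_line1\|/line_height · f` | drift accumulating line by line down the page |
| offset | `(x', y') = (x + dx, y + dy)` | a constant calibration offset |

The slope divisor of 100 px is part of the model definition (the factor
is "pixels of drift per 100 px of x"). Shift computes its distance term
from the *input* y in one pass, not iteratively. Noise accepts an optional
subset mask (off by default: all fixations are perturbed). The noise model
is the only stochastic one and takes an explicit seed.

### Benchmark magnitudes

No canonical magnitudes exist for "low/medium/high" drift, so the package
states its defaults once, relative to the line spacing `L` — the only
scale that matters for line assignment:

* noise SD: `{0.1, 0.25, 0.4}·L`;
* slope and shift: factors chosen so the *maximum* displacement (right
  edge / last line) is `{0.25, 0.5, 0.75}·L`;
* offset: `{0.3, 0.6, 0.9}·L` vertically;
* regression probability: `{0.1, 0.2, 0.3}` (regression trials carry no
  distortion; the six conditions are disjoint).

The high levels deliberately cross the `L/2` snap radius at which purely
positional correction must fail, so the suite separates positional from
relative-position algorithms.

## The nine correction algorithms

All nine output y-values that are members of `line_ys`, never touch x or
duration, and preserve length and order.

* **attach** snaps each fixation to the nearest line, found by binary
  search (`findInterval` plus one neighbor comparison). A y exactly
  midway between two lines goes to the lower-indexed (topmost) line — the
  deterministic choice a stable linear scan would make, and the
  convention used by every snapping step in the package.
* **chain** groups consecutive fixations whose x- and y-displacements
  both stay within `x_thresh`/`y_thresh` (defaults 192/32 px, the
  conventional values in the chain lineage, both exposed) and snaps each
  chain's mean y to the nearest line.
* **cluster** runs k-means with k = number of lines on the y-values,
  orders clusters vertically and maps them to lines top-to-bottom.
  Offset-invariant by construction.
* **merge** splits at x-backtracks beyond 192 px and |Δy| > 32 px, then
  merges run pairs over four phases — (gradient and error), (gradient
  only), (error only), (unconstrained) — accepting the candidate with the
  smallest RMS residual each time, until the run count matches the line
  count. Defaults `gradient_thresh = 0.1`, `error_thresh = 20` px. Runs
  are then mapped to lines in vertical order (or to their nearest line if
  fewer runs than lines survive, e.g. single-line reading under a
  multi-line layout).
* **regress** fits `(slope, offset, sd)` by bounded L-BFGS-B on the
  negative log-likelihood in which each fixation is Gaussian around
  `line_y + slope·x + offset` for its *best* line; fixations are then
  assigned to their maximum-probability line. Defaults: slope in
  ±0.1 px/px, offset in ±L/2, sd in 1–20 px; if the optimizer aborts, the
  best evaluated point is used with a warning.
* **segment** takes the `m − 1` most negative x-displacements as the
  return sweeps and assigns lines 0..m−1 in order. ("Largest negative"
  is our reading of the sweep criterion: a return sweep is the most
  strongly leftward saccade in a trial; ranking by absolute size would
  confuse long forward saccades with sweeps.)
* **split** clusters the x-displacements into two k-means groups; the
  lower-mean group (the sweeps) cuts the sequence, and each segment's
  mean y snaps to the nearest line.
* **stretch** minimizes `Σ|s·y + o − nearest_line_y(s·y + o)|` over a
  bounded `(scale, offset)`; the objective is continuous but flat in
  patches, so the search is derivative-free: a 21×51 grid over the bounds
  followed by Nelder-Mead refinement clamped to the bounds, never
  returning a transform worse than the identity. Defaults: scale
  0.9–1.1, offset ±L/2.
* **warp** computes a dynamic-time-warping alignment between the fixation
  sequence and the reading-order word-center sequence (Euclidean costs,
  unit steps, classic O(n·m) recursion), then sets each fixation's line
  to the modal line of its matched words, ties to the topmost line. The
  backtrack prefers the diagonal move on cost ties, a deterministic
  convention that does not affect the optimal cost.

### Determinism and degenerate inputs

k-means (cluster, split) is seeded with 10 restarts; when the data have
exactly k distinct values those values are used as initial centers
directly, making the clean-recovery case exact and seed-independent.
Cluster requires at least as many fixations as lines; split requires 3+
fixations and non-identical displacements; segment requires at least one
fixation per line; ICC requires two complete rows and non-zero variance —
all are explicit errors, and `run_all_corrections` records per-algorithm
failures while letting the rest proceed.

## Evaluation

* **Accuracy**: fraction of fixations whose assigned 0-based line index
  equals the recorded ground truth. Indices, not pixel values, are
  compared, so a corrector is not penalized for the representation of the
  line position.
* **Per-fixation agreement**: fraction of raters on the fixation's modal
  line (3 of 4 raters together = 75%), overall agreement the mean over
  fixations. This modal-count definition — rather than pairwise percent
  agreement — is the convention used for multi-corrector reading data.
  Cells may be missing; fixations with fewer than two ratings are dropped
  with a warning.
* **ICC(3,1)**: single-rater consistency form from the two-way ANOVA
  without interaction, `(MS_subjects − MS_error)/(MS_subjects +
  (k−1)·MS_error)`, with `F = MS_subjects/MS_error`, `df1 = n−1`,
  `df2 = (n−1)(k−1)`. Among ICC variants this is the one matching a fixed
  rater set that rates every item, with rater differences counted as
  error; incomplete rows are deleted listwise. Line labels are treated as
  interval-scaled values, the standard assumption when ICC is applied to
  ordinal line assignments. Tested to 1e-10 against an independent
  `aov()` decomposition.
* **Group comparison**: two-sided Mann-Whitney U (normal approximation
  with tie correction, delegated to `wilcox.test`) plus Cohen's d from
  the pooled SD.

## The benchmark

`run_benchmark()` generates the 18-trial suite on a given layout (default:
five lines of five words, 50 px spacing, skipping on), corrects every
trial with all nine algorithms, and tabulates accuracy as a 9×18 matrix
with mean/median/SD per algorithm. The whole run is a pure function of
the master seed: per-trial seeds are drawn from it, and
`write_benchmark()` uses fixed numeric formatting so identical runs
produce byte-identical CSVs.

Problem sizes in the test suite are chosen to exercise the contracts at
meaningful scale while keeping the suite quick: oracle equivalence on
1,000 randomized trials, DTW versus exhaustive path enumeration up to
6×6, ICC null simulations with 1,000 replicates, and the
magnitude-monotonicity check averaged over 20 benchmark seeds.

## Known limitations

* All correction is vertical: none of the nine algorithms adjusts x, so
  horizontal calibration error is out of scope.
* The suite's distortion magnitudes are package defaults, not a community
  standard; absolute benchmark numbers are comparable *within* a
  configuration, not across differently parameterized studies.
* Accuracy on synthetic trials bounds what the generator models (see
  above); claims about manual-versus-automated accuracy on real data
  require human-corrected datasets, which this package evaluates
  (agreement, ICC) but does not ship.
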