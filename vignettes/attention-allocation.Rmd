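---
title: "Measuring covert attention allocation: model, estimator, and synthetic experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring covert attention allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnalloc)
library(dplyr)
```

## The problem

Choice experiments measure the allocation of overt behaviour on a
continuous scale; attention research mostly has not. This package
implements a task-and-model pair that does: a cognitive two-armed bandit
in which two digit rows compete for processing during a ~150 ms exposure,
and a linear response model whose inversion returns, per subject, the
probability `p` that the top row was attended. Because the stimuli can be
placed either within one foveal region (0.32° gap) or 15° apart, the same
design also dissociates covert attention from eye movements: in the far
condition correct responses require fixating the correct row, in the
standard condition they do not.

## The model and its assumptions

Conditional on which row is correct,

$$PCT = pA + (1-p)g, \qquad PCB = (1-p)A + pg,$$

where `A` is the probability of a correct response given the correct row
was attended and `g` the correct-guess rate. The inversion

$$\hat p = \frac{PCB - A}{PCT + PCB - 2A}, \qquad \hat g = (PCT + PCB) - A$$

is exact: `forward_response_probs()` followed by `estimate_allocation()`
returns `(p, g)` to machine precision whenever `A != g` (the package
asserts this on 1000 random parameter draws). The model assumes:

* exactly one row is processed per trial (enforced experimentally by
  calibrating the exposure so cued accuracy reaches 85% while 50:50
  uncued performance stays at one-stimulus chance);
* a single guess rate for both rows, `g = 1/7` under uniform guessing
  over the seven probe alternatives — this requires the probe screen to
  contain the correct row's sum exactly once and the *incorrect* row's
  sum not at all, which the stimulus generator enforces;
* a single scalar `A` per subject. `A` is not fitted; it is the mean of
  the top-cued and bottom-cued fractions correct (unweighted, since cued
  trials are balanced in expectation). When Bernoulli row assignment
  leaves a subject with no cued trials for one row, `subject_allocations()`
  falls back to the populated row with a warning rather than aborting a
  cohort analysis.

Estimates outside `[0, 1]` — legitimate under sampling noise — are clamped
and flagged (`clamped_p`, `clamped_g`), never silently discarded; a
denominator within `1e-9` of zero (`PCT + PCB ≈ 2A`) carries no
directional information and is reported as `p_hat = 0.5` with the
`degenerate_denominator` flag. The test of `g` against 1/7 is a Wilcoxon
signed-rank test on square-root-transformed values (many estimates sit
near zero); the p-value uses the exact distribution for n ≤ 25 without
ties and the continuity-corrected normal approximation otherwise, and the
reported statistic is the signed standardized Z with tie-corrected
variance.

## Geometry and AOI maps

All analysis is done in degrees of visual angle relative to the screen
centre (+y up); `extent_to_angle(e, d) = 2·atan(e/2d)`. Defaults encode
the modelled apparatus: 33.7 × 27.3 cm, 1280 × 1024 px, 54 cm viewing
distance, so a 14.22 cm gap subtends 15.0° and a 0.30 cm gap 0.32°.

The exact AOI rectangles used with the original apparatus were never
published; `default_aoi_map()` therefore constructs them programmatically
as six full-width horizontal bands, and the construction is anchored to
the three distances that *are* known: the middle standard-condition bands
(`ST2`/`SB2`) midpoints sit 3.75° from the nearer stimulus row, the outer
bands (`ST1`/`SB1`) 10°, and the region in which a stimulus is embedded
has distance defined as exactly 0. In the far condition the bands are
equal-height and the stimulus rows fall inside `T2`/`B2`. Regions are
half-open (`[min, max)` on both axes) so every point belongs to at most
one region and a boundary point belongs to the upper band — a
deterministic, partition-preserving tie-break. Points up to tracker-noise
distance outside the screen simply classify as "no AOI". Custom maps can
be supplied as JSON (`read_aoi_config()`).

## Fixation detection

`detect_fixations()` mirrors the two published thresholds — 40 °/s
saccade velocity, 100 ms minimum duration — without attempting to
replicate any proprietary event-detection internals (e.g.
pupil-diameter heuristics). Velocity is a 3-sample central difference in
degrees; maximal below-threshold runs of valid samples spanning ≥ 100 ms
become fixations; invalid samples split runs; fixations are classified by
centroid. Streams with fewer than three valid samples yield no events
rather than an error. For the single-AOI filter, a fixation outside every
AOI counts as a distinct point of regard (conservative exclusion), and a
trial with no detected fixation is likewise excluded.

Per-AOI accuracy applies the ≥ 10-visit inclusion rule at the AOI level,
pooled across subjects and conditions (sparser AOIs make conditional
probabilities meaningless); the unfiltered table is retained as an
attribute. Fixation-distribution percentages are column-normalised at
full precision and only rounded (half to even) for display.
Distance–accuracy curves are fitted unweighted by OLS for degrees 1 and 2
— the quadratic captures the floor imposed by the 7-alternative probe.
Rank correlations use average ranks for ties and the Pearson correlation
of the rank vectors; two-point profiles are permitted (they arise when
only the two stimulus regions attract enough visits) but are degenerate
(±1) and should be read as the mutual-exclusivity statement they are.
Exact permutation p-values at n = 6 may differ from values computed by
other approximations.

## The synthetic-data generator

`simulate_cohort()` emulates the study design: 16 subjects, 8 per gap
condition, 2 per probability setting `PT ∈ {0.10, 0.25, 0.75, 0.90}`,
two sessions of 22 cued + 110 uncued trials, 500 Hz gaze. Its defaults
are the study conditions, chosen once:

* **Attention.** `p_t = p_∞ + (0.5 − p_∞)·exp(−λ(t−1))`, an exponential
  approach from indifference with `λ = 0.1` per trial; `p_∞` follows the
  allocation rule `0.15 + 0.78·PT` (probability matching with the
  undermatching expected without feedback; set
  `allocation_intercept = 0, allocation_slope = 1` for exact matching, or
  `learning_rate = Inf` to pin attention at the asymptote). The
  exponential-from-0.5 learning model is the minimal one producing a
  shallower first-session slope; nothing in the analyses depends on its
  exact form.
* **Responses.** Attending the correct row yields a correct response
  with probability `A_true · f(d)` where `A_true = 0.91` (the cohort
  median cued accuracy) and `f` is an effective-field-of-view decay:
  flat to 1.25°, linear down to the guess-rate floor at 12°. The knee and
  slope were calibrated so accuracy stays near 0.8 over 1.25–5°,
  matching effective-field-of-view findings for college-age observers.
  Attending the wrong row triggers a mechanistic guess — a uniform pick
  among the trial's seven probe sums — so the 1/7 rate is emergent.
* **Stimuli.** Digits are uniform on 1–9 (the published task does not
  state the range; 1–9 avoids leading zeros and keeps sums in 3–27);
  rows are redrawn until their sums differ; probe distractors exclude
  the incorrect row's sum. Probe spacing and label assignment are
  randomised per trial.
* **Gaze.** Far-condition subjects fixate the attended row's stimulus
  region (the opposite one with `wander_rate = 0.05`); standard-condition
  subjects hold a central fixation scattered around the screen centre
  (`scatter_deg = 2`) regardless of covert attention — this is the
  mechanism behind the overt/covert dissociation. 22% of trials carry a
  second ≥ 100 ms point of regard in a neighbouring band, linked by a
  20 ms saccade. Within-fixation noise is a slow random-walk drift
  (step s.d. `fixation_jitter_deg/33` per 2 ms sample): white positional
  noise of any visible amplitude would exceed the 40 °/s threshold
  between consecutive samples and no fixation would ever be detected,
  whereas drift keeps velocities near a few °/s, as real fixational eye
  movements do. The gaze clock starts in the preparatory countdown epoch.
* **Exposure calibration.** A staircase from 250 ms in 15 ms steps
  (snapped to the 2 ms frame grid), blocks of 40 trials (three quarters
  cued), descending while cued accuracy ≥ 0.85 and 50:50 uncued
  performance stays inside the binomial 95% band of one-stimulus chance;
  a failing block is retested once so single noisy blocks do not end the
  descent. The subject's psychometric is a logistic in exposure with
  midpoint drawn from 120–152 ms, which places calibrated exposures in
  the 135–180 ms band reported for human subjects. Start value, step and
  block size are design choices (only the calibration goal is published).
  An observer whose asymptotic accuracy cannot reach 85% raises a
  calibration-failure error.

All randomness flows from one root seed via deterministic per-subject
child seeds; every stream regenerates bit for bit.

### What the generator does and does not emulate

It reproduces the statistical structure the analyses assume: trial
counts, probability settings, learning curves, guessing, AOI-dependent
accuracy, two-point-of-regard trials, detectable fixations. It does not
model blinks beyond validity gaps, smooth pursuit, pupil dynamics,
response times, or the idiosyncratic spatial distribution of real
fixations (real subjects visited distant AOIs more than the simulated
ones do). Passing tests therefore validate the pipeline's correctness and
the estimator's statistical behaviour — not claims about any particular
human data set beyond the published summary values used as anchors.

## Problem sizes used in the checks

The test-suite and acceptance computations use cohort sizes matching the
study design (16 subjects × 2 sessions × 132 trials) or smaller slices;
recovery checks use 100 replicate estimates per parameter value, the
matched-cohort slope check 20 replicate cohorts, detector checks ~200
gaze trials plus 10^4 plan-level trials, and the guess-rate convergence
check 10^5 simulated guesses. These sizes make every check's Monte-Carlo
error small relative to its tolerance.

## Known limitations

* AOI midpoint distance is an approximation to the true point of regard,
  as in the original analysis; regions differ in area.
* The published AOI geometry is only approximately recoverable; analyses
  sensitive to exact region bounds should supply a measured map via
  `aoi_map()`.
* ĝ can exceed its clamp boundaries only through noise; clamping biases
  the mean (not much the median) of small-sample estimates slightly
  toward the interior — the Wilcoxon check uses medians and transformed
  values partly for this reason.
* Two-point accuracy profiles make rank correlations degenerate (±1);
  `accuracy_profile_correlation()` reports the pair count so such values
  can be interpreted accordingly.
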