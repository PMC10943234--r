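---
title: "Scoring freezing behavior by unsupervised clustering of frame similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring freezing behavior by unsupervised clustering of frame similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stillframe)
```

## The measurement problem

Freezing — three or more seconds without movement, apart from slow head
movements — is the standard behavioral index of inhibition in
human-intruder-paradigm studies of nonhuman primates, and hand-scoring it
from video is slow and hard to replicate across laboratories. stillframe
scores it from fixed-camera video with a pipeline built around one signal:
the squared Pearson correlation (r²) between each pair of consecutive
grayscale frames, the *similarity score*. When the camera, lighting and cage
are fixed, almost all pixels belong to the static scene, so similarity stays
high even during locomotion (typically above ~0.94 in our calibrations) and
approaches 1 when the animal is still. Freezing, slow ambiguous movement and
overt motion therefore occupy three bands of a one-dimensional signal, and a
three-component Gaussian mixture can find those bands per subject without
training data.

## Pipeline

1. **Similarity trace** (`compute_similarity_trace()`): frames are converted
   to grayscale with BT.601 luma weights and each consecutive pair scored by
   r² of the flattened pixel vectors. Score `i` spans frames `i` and
   `i + 1`, so a session of `n` frames yields `n - 1` scores and all
   durations are score counts divided by fps. Degenerate variance is made
   explicit: two equal constant frames score 1; a constant frame against a
   different frame scores 0, deliberately low so the denoiser treats it as an
   artifact (constant frames come from dropped or blanked video, not from a
   live scene).
2. **Denoising** (`denoise()`): scores at or below 0.93 are artifacts of
   dropped frames or lighting aliasing — genuine behavior does not push
   similarity that low in this recording regime — and are replaced by the
   modal score, then a 3-frame median filter removes isolated flicker. The
   mode of a continuous trace is defined as the center of the most populated
   0.001-wide histogram bin over the *non-outlier* scores (substituting
   outliers with a value estimated from outliers would be self-defeating),
   with ties broken toward the higher bin. The median filter uses
   symmetric-reflect padding so the end scores are filtered against
   themselves rather than against zeros.
3. **Mixture model** (`fit_mixture()`): a three-component 1-D Gaussian
   mixture is fit to the denoised trace by EM. We run 300 independent
   restarts, drawing initial means at the trace's 10th/50th/90th percentiles
   jittered by seeded noise, and keep the fit with the highest
   log-likelihood; with hundreds of restarts the selected optimum is stable
   across seeds on separated data, which is the stability the
   restart-and-reconverge protocol is meant to buy. (An online EM sensitive
   to presentation order would be an alternative reading of that protocol;
   batch EM with restarts is order-free, which is why we chose it, and the
   configuration records the choice.) Components are labeled by ascending
   mean: **motion** lowest, **ambiguous** middle, **freezing** highest,
   because larger frame-to-frame change means lower similarity — the only
   mapping consistent with the physics of frame differencing. The ambiguous
   component exists to absorb scores too close to the boundary to classify
   confidently, making the freezing/motion calls conservative.
4. **Posteriors and bouts** (`posterior_trace()`, `qualifying_frames()`,
   `detect_bouts()`): each score gets posterior membership probabilities for
   the three components, computed in log space so tiny fitted variances never
   produce NaN. A frame-pair *qualifies* as freezing when its freezing
   posterior is at least 0.95 and its score is not anomalous for the freezing
   component under a lower Tukey quartile fence (below). Runs of at least 90
   consecutive qualifying frame-pairs (3 s at 30 fps) become freezing bouts;
   shorter stillness is never freezing, and any movement splits a bout — 4 s
   of freezing, movement, then 10 s of freezing is two bouts of 4 s and
   10 s. **Motor activity** is the sum over the session of the motion
   posterior, a unitless index bounded by the trace length.
5. **Semi-automation** (`override_components()`, `run_session()`): an animal
   that almost never or almost always moves cannot support three distinct
   components. Such fits carry an edge-case flag (a component weight below
   0.01 or adjacent means closer than 0.005), and `run_session()` refuses to
   auto-score them: it returns a review-required status with frame ranges of
   diagnostic clips instead of a bout table. A reviewer who has watched the
   clips supplies component means directly; the override need not be precise,
   because in these degenerate sessions the only requirement is that all
   frames classify the same way. Tense body posture, part of the classical
   freezing definition, is deliberately not modeled: human raters agree on it
   barely above chance, so a pixel-based tool should not pretend to score it.

## The qualifying rule, and why the default fence is "far out"

The anomaly component of the qualifying rule is quartile-based: with the
freezing component's Gaussian quartiles `Q1`/`Q3` (the 75% level is
configurable via `freezing_quantile`), scores below
`Q1 - tukey_k * (Q3 - Q1)` are rejected regardless of posterior. Two
decisions here deserve explanation.

*Why not require scores in the rightmost quartile itself?* A rule that only
accepts scores at or above the freezing component's Q3 caps the acceptance
rate for genuinely frozen frames at the component's top-quartile mass, about
25% — and since a bout needs 90 *consecutive* qualifying frames, the
probability of any bout under such a rule is essentially zero
(`0.25^90`). No tool validated at ~84% sensitivity against human raters can
be operating that way. We therefore read the quartile machinery as the
anomaly screen and the posterior threshold as the classifier; the literal
top-quartile conjunction remains available as
`bout_config(strict_quantile_cut = TRUE)` for sensitivity analyses.

*Why `tukey_k = 3` rather than the conventional 1.5?* For a Gaussian
component the 1.5 fence sits 2.70 sd below the mean and marks ~0.35% of the
component's own draws as anomalous. Scattered uniformly through a freezing
interval, those rejections split qualifying runs; fragments shorter than 90
frames are discarded, so a per-frame rejection rate of a third of a percent
costs 10–15% of true freezing time. Tukey's "far out" multiplier of 3 places
the fence 4.72 sd below the mean (rejection rate ~1e-6), preserving the
screen against gross anomalies without shattering bouts. The conventional
fence remains one keystroke away in the configuration.

## Session statistics

`split_half_test()` compares per-subject freezing totals between session
halves with an independent-samples, equal-variance t test, giving
`2n - 2 = 34` df for an 18-subject cohort; a paired test would be the more
natural design for within-subject halves, but the independent-samples form
is the one this literature reports, so it is what the function computes (the
choice is visible in the df). Bouts straddling the midpoint are apportioned
to each half by overlap. `minute_bins()` reports the fraction of each
minute's scores inside a bout, and `grand_mean_trend()` correlates the
cohort grand mean against bin index as a drift (habituation) test, flagging
the constant-series case where the trend is undefined. `correlate()` is
Pearson correlation with a Fisher-z 95% CI; freezing durations are
right-skewed, so the conventional transform is `ln(y + 1)` — the +1 offset
is needed because a subject may never freeze.

`cohen_kappa()` implements chance-corrected agreement from the 2x2
marginals, `round_robin()` averages it over rater pairs, and `consensus()`
takes the per-segment majority with exact ties coded non-freezing — the
conservative direction, consistent with requiring a majority before calling
a "true" freezing outcome. The significance of an observed kappa is assessed
by a seeded label-permutation test (`kappa_permutation_test()`), our choice
in the absence of a canonical test.

## The synthetic generator

No public videos accompany this method, so the package ships a generator
with two levels, both driven by a common ground-truth schedule of
freezing/ambiguous/motion intervals with uniformly drawn dwell times
(freezing dwells start at 120 frames so every true bout is detectable under
the 3 s rule):

* `render_session()` draws actual frames: a Gaussian blob subject over a
  static noise texture, plus small per-frame sensor noise. Displacement per
  frame is zero when freezing, ~0.9 px jitter when ambiguous (a slow head
  movement), and ~2 px steps in motion, with near-constant step magnitude
  and random direction — locomotion has a characteristic speed, and
  isotropic Gaussian steps would smear each state's score band into a
  Rayleigh-wide distribution. Defaults were calibrated once so the
  state-conditional similarity means land near 0.955 / 0.99 / 0.998 with
  compact spreads: the trimodal, high-similarity regime fixed-camera cage
  video occupies.
* `simulate_trace()` skips rendering and draws each score from its state's
  Gaussian (defaults 0.955 / 0.975 / 0.995, sds 0.004 / 0.004 / 0.002),
  truncated to [0, 1] — truncation rather than clipping, so no probability
  mass piles up at the bounds and the mixture stays identifiable. This is
  the fast path for statistical tests at 10^4 scores.

What the generator does *not* emulate: lighting drift, camera shake,
occlusion, multi-animal scenes, posture, and the heavy quantization of real
8-bit video. Passing tests on synthetic data therefore demonstrate that the
algorithmic chain is correct and well-calibrated for its assumed regime, not
that the tool will hit the same numbers on arbitrary real footage — on real
data the semi-automated review path exists precisely because some sessions
violate the three-band assumption.

## Numerical choices and degenerate inputs

* EM uses a variance floor of 1e-8; a component collapsing onto the floor or
  starving below 1% weight triggers the edge-case path rather than silent
  acceptance. Convergence is an absolute log-likelihood change below 1e-8,
  capped at 500 iterations.
* Posteriors and the EM E-step guard against underflow (log-space and
  nearest-component hard assignment, respectively); no input produces NaN.
* An all-identical trace is refused with a degeneracy error that routes to
  manual override; a trace entirely at or below the outlier threshold is
  refused as degenerate rather than "denoised" into fiction.
* Median filtering is not idempotent on arbitrary sequences (alternating
  patterns keep changing on repeated passes); on the piecewise-stable traces
  it is designed for — state dwells far longer than the kernel — a second
  `denoise()` pass is a no-op, and the test suite pins exactly that class.
* All randomness (schedules, renders, simulated traces, EM restarts, segment
  sampling, permutation tests) flows through explicit integer seeds; a fixed
  configuration reproduces outputs byte-for-byte, and every output file
  carries a sidecar with the config hash, seed and package version.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic data
at sizes we consider representative while staying quick on a laptop:
mixture-recovery runs use ten sessions of 9,000 scores (five minutes at
30 fps) at the full 300 restarts; rendered-video checks use five 60 s
sessions at 80x80 px plus four 180 s sessions for the segment-sampling
protocol; the cohort analysis uses 18 subjects of five minutes each. Longer
sessions change nothing structurally — cost is linear in frames.

## Known limitations

* The similarity score is global: a large lighting change or camera bump
  reads as motion. The optional crop rectangle mitigates but does not remove
  this.
* Perfectly anticorrelated frames would also score r² = 1; this cannot arise
  in fixed-camera cage video and is accepted.
* The three-band assumption fails for animals that freeze almost always or
  almost never; the tool detects this and demands review rather than
  guessing.
* Component labels assume more movement means lower similarity. If a rig
  produced the opposite ordering (it should not), the labels — which are
  assigned by mean — would still be attached by ordering, not by behavior.
* Bout timing ignores the half-frame offset between a score and the pair of
  frames it spans (≤ 33 ms at 30 fps).
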