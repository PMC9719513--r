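---
title: "Methods: behavioral scoring, photometry and ensemble statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioral scoring, photometry and ensemble statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avoidance)
```

This vignette is the package's own account of the analyses it implements:
the models and conventions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## Arena geometry and zone scoring

Open-field sessions use a square box (default 40 cm) divided into a
center square (innermost 20 × 20 cm), a peripheral band (within 5 cm of
any wall) and the middle zone between them. The plus maze has a 5 × 5 cm
central square, two open arms along x and two closed arms along y, each
30 × 5 cm. Coordinates are in cm with the origin at the lower-left corner
of the bounding box.

Boundary conventions had to be fixed somewhere: we close boundaries
toward the more extreme zone — a point exactly on the center-square edge
is center, a point exactly 5 cm from the wall is peripheral, and a point
on the maze's center/arm boundary belongs to the arm. This makes the
partition deterministic and keeps "within 5 cm" inclusive. Every
in-bounds frame receives exactly one label, so per-zone durations always
sum to the trial duration to within one frame interval — a conservation
property the tests assert on every generated session. Tracking glitches
(points beyond a 1-cm tolerance outside the arena) are flagged and
excluded from durations rather than clamped, so they can be counted and
inspected.

## Approach–retreat bouts

The original scoring of approach ("began to move toward the object") and
retreat was manual. `detect_approach_retreat()` is an automatic surrogate
with every threshold exposed: the distance to the object is smoothed with
a centered 0.5-s moving median; alternating extrema of the smoothed
distance are extracted with a 1-cm hysteresis; a candidate descent becomes
an approach when it covers ≥ 5 cm, lasts ≥ 0.5 s and averages ≥ 2 cm/s;
the approach ends at the distance minimum (the turning point), which is
also the retreat's start. Because the moving median flattens the minimum
into a short plateau, the exact turning point is recovered from the raw
distance within one smoothing window, and bout edges are refined to the
contiguous span where the radial speed exceeds half the threshold — slow
drift along the wall before a dash is not counted as approach. None of
these values comes from the source experiments (which did not report
kinematic thresholds); they are stated defaults, and the generator-based
tests require the detector to recover ≥ 90% of planted bouts with onsets
within two frames.

Bouts of the same type separated by less than 1 s are both excluded
(not merged) before any correlation analysis, mirroring how rapid
re-engagements are discarded; the operation is idempotent, which the
tests check by applying it twice.

## Photometry processing

Raw fluorescence (nominally 500 Hz) is trend-adjusted for photobleaching
before anything else. The default model is a mono-exponential
`a·exp(−t/τ) + c` fitted by Levenberg–Marquardt least squares; the fitted
curve minus its final value is subtracted, an additive correction that
preserves units and transient amplitudes relative to the local baseline.
The fit uses a decimated grid of at most 2,000 samples — the trend is
slow, and the full 500-Hz grid adds nothing but runtime. A running
8th-percentile baseline (60-s window, evaluated on a coarse grid and
interpolated) is available as an alternative and is the automatic
fallback when the exponential fit fails to converge. The exact detrending
of the original custom code is unknown; both methods and their parameters
are recorded in the output metadata.

ΔF/F is (F − F₀)/F₀ with F₀ the mean of the adjusted signal over a
context-specific window: the pre-object window for the open field, the
pre-stimulus window for new-cage and home-cage recordings (both half-open,
ending strictly before the stimulus), and the whole trial for the plus
maze (closed, so whole-trial ΔF/F averages exactly zero). ΔF/F is a
fraction internally and a percentage only at presentation.

Zone-resolved ΔF/F matches each video frame to the nearest photometry
sample — no interpolation of the raw signal — and averages within zones.
Event-aligned averages follow the nested convention: average across
events within an animal first, then across animals, with SEM across
animals; with unbalanced event counts this deliberately differs from
pooling all events, and a test constructs a case where the two orders
disagree. Partial windows at the recording edges are dropped, not padded.
Stimulus-locked summaries tile consecutive non-overlapping 30-s windows
backward and forward from the stimulus over the whole recording.

The binarized activity–behavior correlation thresholds the
trend-adjusted signal (not ΔF/F, matching the convention that the
threshold is applied to the F value) at mean + 2 SD over the full
analyzed epoch. Calcium transients are positive deflections, so the
default is upper-tail; a two-sided option exists. The behavior mask is 1
on frames inside retained approach–retreat bouts. Spearman's rank
correlation on two binary series equals the phi coefficient — an identity
the tests verify over a thousand random mask pairs — and the p-value uses
the t approximation, appropriate at these series lengths. For
approach-end analyses the first approach is always excluded to rule out
initial-exposure effects, and the last approach contributes no latency
pair.

## Single-unit analysis

Spike trains are binned at 250 ms around event onsets; analysis windows
are 5 s before/after onset for behaviors (object approach, urine sniff)
and 5 s before / 10 s after for discrete events (urine introduction,
open-arm entry). Rates are averaged across events and every bin is
Z-scored against the mean and *population* SD of the pre-onset bins of
that averaged trace. The per-event-baseline alternative was not specified
in the source convention; the event-averaged choice is logged in the
output. A unit is excited when Z > 2 in two consecutive bins inside the
event-specific decision window (2 s for behaviors, 10 s for urine
introduction, 7.5 s for open-arm entry), inhibited symmetrically. Units
whose pre-onset SD is zero are reported "unclassifiable" — a category
distinct from "none", keeping denominators honest. When both criteria
fire, excited takes precedence and the call is flagged.

The classifier's false-positive rate under homogeneous Poisson firing is
not assumed analytically: the tests estimate it with a 10,000-replicate
Monte-Carlo implementation of the rule and require the full pipeline's
null call rate to match within binomial error. Sensitivity is required to
exceed 90% for units with a 3× gain lasting 2 s over ≥ 20 events.

Ensemble overlap between two tuned sets uses the 2×2 membership table
over the common unit population. The two-sided Fisher exact p is computed
in-package by hypergeometric enumeration (summing all outcomes no more
probable than the observed one); `stats::fisher.test` and `stats::dhyper`
serve as independent oracles in the tests, over every table with total
n ≤ 40. The chance level reported alongside is the independence
expectation n_A·n_B/n_total — the source convention never defined one for
single units, so the independence expectation is stated explicitly in the
output. Sidedness is two-sided by default with a one-sided option.

Quality control implements only the inter-spike-interval criterion
(fraction of ISIs below 2 ms must be under 1%); spike sorting itself,
isolation distance and L-ratio are out of scope, as sorted spike times
are the package's input.

## catFISH statistics

The convergence rate is n_both/n_intron — the fraction of
second-stimulus-activated cells also activated by the first stimulus. The
chance level is formalized as n_exon/n_vgat, the first-stimulus
activation fraction: under independent activation the convergence rate
equals it in expectation, and with ~20% first-epoch activation this
reproduces the familiar ~20% chance level. The group-level test behind
"higher than chance" was never named in the source convention; the
package reports a per-animal exact binomial test (n_both successes in
n_intron trials against p = chance, one-sided greater, since the
scientific question is an excess) plus group means ± SEM, leaving the
group inference explicit rather than implicit.

## The synthetic-data generator

The generator produces data with the *statistical structure the analyses
assume*, with ground truth recorded for every planted quantity. It is a
semi-Markov behavioral model, not a mechanistic agent.

* **Open field**: dwell-and-relocate movement along the wall with
  occasional interior visits (probability 1 − `wall_preference_weight`),
  and planted straight approach excursions to `approach_depth_cm` (3 cm)
  from the object at `bout_speed_cm_s` (15 cm/s) after object
  introduction, at `bout_rate_per_min` (2/min). Defaults: 20-min session,
  object at half time, 25-Hz frames.
* **Plus maze**: arm visits from the center with open-arm probability
  `(1 − epm_open_avoidance)·(1 − slope·t/T)`; entries, exits and depths
  recorded. Defaults give roughly 15–20% open-arm time, typical of a
  first EPM exposure.
* **Calcium**: latent drive = `distance_gain` × proximity, where
  proximity is `max(0, 1 − d/d_wall)` with `d_wall` the object-to-wall
  distance — zero while the animal hugs the wall, maximal at the object.
  The drive is convolved with a double-exponential kernel (0.2-s rise,
  1.5-s decay, unit area) consistent with a slow indicator, multiplied
  onto a bleaching exponential (τ = 2000 s) and baseline (100 a.u.), with
  Gaussian noise (SD 1). `distance_gain = 0` yields the control
  condition. Kernel and bleach parameters are implementation choices, not
  claims about the source preparation.
* **Spikes**: inhomogeneous Poisson by thinning at `baseline_rate_hz`
  (5 Hz) with an `event_gain` (3×) for `gain_duration_s` (2 s) after each
  event a unit is tuned to, followed by a 3-ms absolute refractory period
  (without one, a 5-Hz Poisson train sits exactly at the 1% ISI-violation
  boundary, which no well-isolated unit should).
* **catFISH**: per-cell Bernoulli activation; intron⁺ with probability
  `p_second_marginal` (0.15), exon⁺ with probability
  `conditional_overlap_q` (0.75) given intron⁺ and with the
  marginal-preserving probability otherwise. Infeasible triples are
  rejected with the violated inequality. `p_first = 0.2` and `q = 0.75`
  match ~20% first-epoch activation and ~70–80% convergence.

One parameterization choice deserves a note: `overlap_rho` is defined
directly as P(unit ∈ A | unit ∈ B), the quantity the overlap estimator
n_AB/n_B measures. ρ = 1 nests ensemble B inside A and ρ = 0 makes the
ensembles disjoint; independence corresponds to ρ = `tuned_fraction_A`.
Defining ρ as the measured conditional probability is what makes the
parameter-recovery requirement (estimate within ±0.1 of ρ at 100 units)
a well-posed check of the full classify-then-overlap path.

Each sub-generator draws from its own pseudo-random stream derived from
the master seed, so adding a generator never perturbs the others, and a
fixture bundle regenerated with the same configuration is byte-identical
(floats are serialized at 6 significant digits; spike times at 10, so
reread trains stay strictly sorted).

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: motion and hemodynamic artifacts
(no isosbestic channel exists or is needed here), indicator
nonlinearity and saturation, tracking noise and body-part ambiguity,
non-Poisson spike statistics (bursting, adaptation), electrode drift, and
any feedback of neural activity onto behavior. The open-field cohort
script couples gain and wall preference across simulated animals to
emulate individually varying anxiety phenotypes; that coupling is a
cohort-level choice of the script, not a claim of the generator.

## Numerical choices and degenerate inputs

* Convolution uses FFT with zero-padding to a 2·3·5-smooth length; naive
  use of `stats::convolve` can land on near-prime lengths where R's
  mixed-radix FFT degenerates to quadratic time.
* `stats::nls`/`minpack.lm::nlsLM` exponential fits are attempted on a
  ≤ 2,000-point decimated grid with data-driven starting values; failure
  falls back to the running percentile with a warning.
* Constant traces (SD = 0) are an error for binarization; constant masks
  give an `NA` correlation with a `degenerate` flag; F₀ ≤ 0 after
  detrending is an error rather than a silent sign flip.
* Zero-length epochs, events outside the recording, and epochs without
  frames error or warn explicitly; partial event windows are dropped with
  a count.
* Reports serialize floats at 6 significant digits so that reruns are
  byte-identical and diffs are meaningful.

## Problem sizes

The test-suite simulations use 400–600-s sessions at 100-Hz photometry
and cohorts of 4–8 animals, and the heavier checks (10,000-replicate
classifier null, 500 cells × 4 animals, 100-unit ensembles, all 2×2
tables with n ≤ 40) run in well under a minute each; these sizes were
chosen so the whole suite completes in about half a minute while every
tolerance stays comfortably inside the estimators' sampling error at that
scale. The analysis scripts use the same sizes. The generator's defaults
(20-min open-field sessions at 500-Hz photometry) match the recording
conditions the analyses were designed for and are what
`make_fixture_bundle()` emits.

## Known limitations

* The bout detector is a surrogate for manual annotation; its thresholds
  are defaults, not fitted to human scoring.
* "Moving time" for velocity (frames with 0.5-s-smoothed speed above
  1 cm/s) is our formalization; the original extraction tool's definition
  is not documented.
* Freezing, stretch-attend postures, jumps and head dips are consumed as
  pre-annotated labels; the package does not detect them from
  trajectories.
* Whether binarization should use the adjusted F or ΔF/F is ambiguous in
  the source convention; both are supported, adjusted F is the default.
* The per-animal binomial test for catFISH is our machine-checkable
  analogue of a group test that was never specified.
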