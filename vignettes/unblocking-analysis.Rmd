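---
title: "Classifying and decoding lateral-OFC single units in a Pavlovian unblocking task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying and decoding lateral-OFC single units in a Pavlovian unblocking task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unblockr)
```

## The task and the scientific question

In an odor-guided unblocking procedure, a rat is first trained that an
*initial* odor predicts a medium-sized drop of reward. During unblocking,
three novel odors are introduced in compound with the initial odor (200 ms of
the initial odor, then 800 ms of the novel odor): one paired with the same
reward (the *blocked* cue, which should acquire no association), one with a
larger reward (*upshift*), and one with a smaller reward (*downshift*).
Learning spans two recording days, followed by an unrewarded probe test in
which time spent in the reward well after each cue indexes the learned reward
expectation.

The analytic question is what single units in lateral orbitofrontal cortex
signal about these cues: a monotone *value* code (upshift > blocked >
downshift, each step significant), *tuning* to individual cues, a
*predictive* code for the two cues that signal a change, cue *salience*
(all three novel cues), or unselective *sensory* responses to every odor.
`unblockr` implements that taxonomy, the supporting peri-event statistics,
trial-resolved significance maps, pseudo-ensemble decoding of trial type,
and the behavioral analyses — all driven by a synthetic session generator
with ground-truth unit labels, so every stage of the pipeline can be
exercised and calibrated without recorded data.

## Epoch statistics

All firing measures are trialwise rates in half-open windows (a spike on a
boundary belongs to the later bin):

* **ITI baseline** — the 2 s preceding house-light onset.
* **Odor period** — 300–1300 ms after odor onset, which tracks the novel
  odor's time in the port on compound trials. An alternative convention, the
  1 s from novel-odor onset itself (200–1200 ms after odor onset), is
  available via `default_epochs("post_novel")`; the two windows differ by a
  100 ms shift and the published text supports both readings, so the window
  is data, not code.
* **Normalized firing** — odor-period rate minus ITI rate, in spikes/s.

Odor-period analyses drop the first seven trials of each type
(`min_trial = 8`), except trialwise heat maps and trialwise decoding, which
exist precisely to show early learning. Incomplete trials are retained in
session files but flagged and excluded from all rate analyses; the original
task restarts aborted trials and their analytic treatment is unstated, so
exclusion is this package's choice.

## The responsiveness screen and taxonomy

Units with mean baseline below 10 Hz are screened per odor with a Welch
two-sample t-test of trialwise odor-period rates against trialwise ITI rates
at `alpha = 0.01`, uncorrected (the source analysis applies no
multiple-comparison correction). Two defaults deserve comment:

* **One-sided tests.** The screen is explicitly a screen for *increases*
  in firing, so `alternative = "greater"` is the default. This also makes
  the screen's false-positive rate equal its nominal level (a two-sided test
  combined with a direction gate would operate at `alpha/2`); the two-sided
  variant is an argument away.
* **Pooled ITI baseline.** The ITI precedes the house light, before the
  animal can know the upcoming cue, so the ITI sample is cue-independent by
  design. The default therefore pools ITI rates across all analyzed trials,
  roughly quadrupling the baseline sample. At the study conditions the
  generator emulates (~2 spikes/s modulation over ~3 Hz baselines, 30
  trials per cue, 23 after the trial filter) this raises per-odor detection
  power from roughly 0.85 to above 0.95, which matters most for the salience
  category, whose recovery requires three simultaneous detections.
  `baseline = "same"` restores the per-odor baseline.

Value coding is defined operationally: at least one excitatory odor response,
plus significantly more odor-period firing on upshift than blocked trials and
significantly less on downshift than blocked trials (directional
between-trial-type Welch tests at `alpha = 0.01`).

Categories are assigned by a fixed decision order — nonresponsive; sensory
(all four odors, not value-coding; excluded from the associative
populations); value; initial-only; single-cue tuned; predictive (upshift and
downshift, not blocked); salience (all three novel cues, not initial); and a
residual mixed class. Tuned, predictive and salience calls all require the
initial odor to be non-significant; units excited by the initial odor plus a
subset of novel odors fall into the mixed class, mirroring how such cells
are treated narratively rather than categorically in the source analysis.
The uniformity of tuned-cell counts across the three novel cues is tested
with a chi-squared goodness-of-fit test against equal expectation (df = 2):

```{r chisq}
category_uniformity_test(c(19, 16, 16))
```

## Heat maps and significance maps

Trial-resolved population maps use 150 ms windows advanced in 50 ms steps
away from novel-odor onset, baseline-corrected per trial (or normalized to
the initial cue's same-window mean), averaged across units. Significance per
(trial, window) cell is a one-tailed one-sample t-test across units of the
corrected rates; the threshold is a parameter because the published maps use
both 0.001 and 0.01. Zero-variance cells (possible in principle with
deterministic inputs) are reported significant when their mean is positive,
with a warning — a convention, flagged as such.

## Pseudo-ensemble decoding

Units recorded in different sessions are stacked into pseudo-trials aligned
by within-type trial index, so the learning stage is preserved; classes are
truncated to the common trial count. The classifier is a linear discriminant
with the pooled covariance shrunk halfway toward its diagonal
(`lambda = 0.5`) plus a small ridge, cross-validated by
leave-one-pseudo-trial-out; the shrinkage keeps the decoder well-posed at
the small trial counts and short windows used here, and a multinomial
logistic alternative sits behind `method = "multinom"`. Four trial types are
decoded, so chance is 0.25.

Two read-outs are provided:

* **Over time** — per-100 ms-bin accuracy, smoothed with a trailing
  three-bin average. The summary accuracy over the window following
  novel-odor onset (500 ms for tuned cells, 400 ms for unrestricted
  populations) scores each window bin of a held-out trial as its own
  prediction, so the binomial n is trials × window bins — the
  bins-as-additional-trials convention of the source analysis, capped at
  exactly that product.
* **Over trials** — accuracy in sliding windows of 10 (or 4) trials per
  type, using each unit's mean rate across the accuracy window as the
  feature, one scored prediction per held-out pseudo-trial. No bin
  augmentation is applied here: bin votes within a trial are correlated, and
  inflating n would make early-learning windows spuriously significant.
  The Spearman correlation between window index and accuracy summarizes the
  learning trend.

Significance in both cases is the exact upper-tail binomial probability of
the observed number of correct predictions under chance.

## The synthetic generator

`generator_config()` encodes the study conditions:

* **Trial structure** — four randomly interleaved trial types; 30 trials
  per novel odor per learning session (task range 20–40) plus 30 reminder
  trials; probe day with 10 reminder trials per type followed by up to 10
  unrewarded presentations of each novel odor interleaved with rewarded
  initial-odor trials. Inter-trial intervals are uniform on 4–8 s (the task
  description leaves the ITI open; only the 2 s pre-light window matters
  analytically).
* **Spiking** — each unit is an inhomogeneous Poisson process: a
  homogeneous baseline (lognormal across units, median 3 Hz, so almost all
  units sit under the 10 Hz screening cap) plus an added rate on the unit's
  preferred trial types during the 1 s odor analysis window, so the nominal
  2 spikes/s modulation of tuned cells is exactly the analysis-epoch effect
  size. Spikes are realized by superposing the baseline train with
  per-window Poisson extras, which is exact for additive piecewise-constant
  rates (thinning would sample the identical law); the contract is the rate
  function, not the algorithm. Timestamps live on a 0.1 ms grid, the only
  biophysical floor imposed — no refractoriness, no cross-unit correlation.
* **Learning** — cue modulation scales with a logistic factor of the
  per-cue cumulative trial count (day 2 continues day 1's count), midpoint
  trial 25 and scale 5. These values were calibrated to the qualitative
  learning pattern the generator must emulate: ~0.8% of asymptote on the
  first trial, late-day-1 responses that trend upward yet decode near
  chance, and near-asymptotic day-2 responses that decode well. Sensory and
  initial-only profiles carry no ramp (those responses exist from the start
  of training). Value cells add 0×, 1×, 2× the modulation on downshift,
  blocked, upshift trials.
* **Category mix** — the default unit mix keeps the tuned populations
  comparable in size, salience sizeable, and value rare, qualitatively
  matching the published taxonomy proportions.
* **Behavior** — response latency (well entry minus odor offset) is
  lognormal with a novelty surcharge on novel-cue trials that decays over
  the first few trials and shrinks on day 2, producing the trial effect and
  trial × day interaction of the latency analysis. Probe time-in-well means
  start at 4 / 3 / 2 s for upshift / blocked / downshift and decay
  exponentially toward a 1 s floor (extinction), with trial-level noise
  (sd 0.8 s) and a rat-round random intercept (sd 0.3 s).

What the generator does *not* emulate — drifting baselines, bursting,
correlated noise across simultaneously recorded units, unit attrition
between days, session-to-session electrode movement — bounds what passing
tests show: they certify the statistical machinery and its calibration
under the assumed data model, not robustness to every pathology of real
recordings.

## Numerical conventions

* Windows are half-open; moving averages are trailing with shortened output
  (no edge padding is invented).
* The screen refuses units with fewer than two analyzable trials per odor
  and marks them `unanalyzable` rather than dropping them.
* Latency correlations require three usable trials and non-degenerate
  variance.
* The factorial ANOVAs pool trials as replicates (matching the trial-level
  residual df of the published behavior analyses); a per-rat-round
  aggregation mode exists because pooling inflates df. With all-equal input
  the F statistics are reported as 0 rather than 0/0.
* All stages are deterministic given a seed; the pipeline derives per-round
  seeds from a master seed so partial re-runs reproduce.

## Problem sizes used in the shipped checks

The package's own verification runs use study sizes chosen to estimate each
property with adequate precision while remaining quick: 2000 null units for
screen calibration, 20 seeds of the ~130-unit default study for taxonomy
recovery, 20-unit ensembles for the decoding contracts, 10 seeds for the
day-1/day-2 learning contrast, and 10 seeds of 8-round studies for the
behavioral contrasts.

## Known limitations

* The value-coding definition has modest power at the nominal 2 Hz step
  size with 30 trials per cue (both directional tests must reject at 0.01);
  genuine value cells are therefore under-called, consistent with their
  rarity in the source taxonomy — a property of the definition, not a bug.
* The exact cross-validation scheme and bin-augmentation rule of the
  original decoding analysis are not recoverable from its description;
  published accuracy curves are qualitative, not numeric, targets, and this
  package's rules (LOO; augmentation only in the time-resolved window
  summary) are explicit and configurable.
* The control task variant (no compound cue) reuses every analysis with
  relabelled cues and is exercised in tests, but its defaults have not been
  calibrated as carefully as the blocking variant's.
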