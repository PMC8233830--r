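---
title: "Classifying walking environments from stance-phase surface EMG"
author: "GaitEnv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying walking environments from stance-phase surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GaitEnv)
```

## The problem

A walking assistive device (exoskeleton or powered prosthesis) must know
what terrain its user is on — flat ground, stairs up or down, a ramp up or
down — to select an appropriate control mode. Lower-limb surface
electromyography (sEMG) carries that information: the activation pattern
of the leg muscles during the stance phase of gait changes systematically
with terrain, most strongly at the ankle, where push-off demand rises on
ascent and collapses on descent.

GaitEnv implements the full analysis for this five-environment
classification task: flat-ground walking (FGW, label 1), upstairs (US, 2),
downstairs (DS, 3), uphill (UW, 4) and downhill (DW, 5). Eleven muscles
are monitored: RF, VL, VM (quadriceps), ST, BF (hamstrings), TA
(dorsiflexor), Sol, MG, LG (plantarflexors / triceps surae), FHL and EDL
(metatarsophalangeal flexor/extensor). Force-plate and sEMG channels are
sampled synchronously at 1200 Hz.

## The processing model

**Stance segmentation.** Initial heel contact is the first frame in which
the vertical ground reaction force (vGRF) exceeds 20 N; toe-off is the
first frame after the post-contact force peak at which the force falls
back below a threshold. The literal event definition for toe-off is the
force "returning to 0 N"; an exact-zero criterion never fires on a real
force plate with noise, so `detectStance()` defaults to a symmetric 20 N
offset threshold and offers `offsetMode = "zero"` for noiseless synthetic
traces. Requiring the offset crossing to follow the force *peak* makes the
detector robust to sub-threshold wobble during weight acceptance. Windows
are half-open sample intervals (`IRanges` of loaded frames), so
concatenated windows never double-count a frame; a minimum plausible
stance of 0.2 s guards against spurious contacts.

**Linear envelopes.** Each raw sEMG channel is band-passed (4th-order
Butterworth, 20–500 Hz), full-wave rectified, then low-passed (4th-order
Butterworth, 10 Hz). Both filters are applied zero-phase
(forward–backward), which doubles the effective order; offline envelope
extraction must not introduce phase lag that would desynchronize muscles,
and no causality requirement applies after the fact. Filtering runs on the
*full* trial before any cropping, so filter transients fall in the swing
pads rather than inside the stance window. Small negative ringing after
the low-pass is clamped to zero so envelopes are valid nonnegative
activation curves.

**Normalization.** Envelopes are divided, per subject and muscle, by the
peak envelope amplitude reached *inside the stance phase* during that
subject's flat-ground trials. With five flat-ground trials per subject the
singular "the flat-ground trial" is ambiguous; the default takes the
maximum across all of them (`normalizationMode = "max"`), which is the
more stable estimator, and a per-single-trial mode is provided. Because
flat ground is the reference, normalized activations in other environments
may exceed 1.0 — that headroom is informative, not an error.

**Time normalization.** The stance segment of each envelope is linearly
interpolated onto 1000 equally spaced points spanning 0–100 % of stance,
endpoints included. Profiles for a muscle set are concatenated in the
fixed canonical order (RF, VL, VM, ST, BF, TA, Sol, MG, LG, FHL, EDL), so
the all-muscle input vector has 11 000 components.

## The classifier

A single-hidden-layer fully connected network maps the concatenated
profile to five softmax outputs: input → hidden (ReLU) → 5. Training
minimizes mean softmax cross-entropy with Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$).

The source analysis states the architecture, loss and optimizer but none
of the remaining hyperparameters; GaitEnv's defaults are hidden width 100,
learning rate $10^{-3}$, 200 epochs, mini-batches of 128, He-uniform
initialization. Two hundred epochs is comfortably past convergence for
these well-separated profile inputs (the per-epoch loss trace is kept on
the model so this is checkable), and the modest update count keeps the
18-experiment grid tractable on a single core. With very small training
sets the batch size should be lowered so enough Adam updates occur — the
test suite does exactly that for its miniature studies. All settings are
config-exposed (`annConfig()`) and echoed into every report.

The dataset split is 80 % train / 20 % test, stratified by environment so
that each class contributes 27 of its 135 trials to the test set at the
default study shape. Trial-level splitting matches the published design
but leaks subject identity across the split (a subject's other trials are
in training); `splitDataset(mode = "subject")` holds out whole subjects
instead, and the choice is recorded in the report rather than made
silently. Ties in the softmax argmax break toward the lowest label.

The muscle-subset grid (`runSubsetExperiments()`) retrains a *fresh* model
per subset — never a masked shared model — for the full set, the six
per-joint flexor/extensor groups and each single muscle: 18 experiments.
Because each muscle occupies its own 1000-point block and the processing
chain is per-muscle, restricting a dataset to a subset is exactly
row-subsetting, which is what `subsetMuscles()` does.

## Evaluation

Counts are authoritative: the `ConfusionMatrix` stores 5×5 integers (rows
actual, columns predicted, order FGW…DW) and every metric derives from
them. Accuracy is trace/total × 100. Sensitivity and specificity are
one-vs-rest: the current environment is positive, the other four negative,
so TP is the diagonal cell, FN its row remainder, FP its column remainder,
TN the rest. Percentages are rounded to one decimal only at serialization;
averaging printed percentages instead of counts is exactly how a 68.1
becomes a 68.16, which is why the package never does it.

Published row-percent matrices are convertible back to exact counts when
the per-class test count is known (`countsFromPercent()`, 27 per row
here). The packaged reference matrices reproduce every published accuracy
this way. Three quirks of the source tables are handled explicitly rather
than absorbed: the printed uphill specificity (100) contradicts its own
matrix, which contains one DW→UW error and hence gives 107/108 = 99.1 %;
and three matrix rows (the EDL group block's FGW row, VL's UW row, VM's US
row) carry off-diagonal misprints so their recovered counts do not sum to
27. `checkPrintedTables()` flags all of these and verifies everything
else; accuracies are computed over the known test-set size (135) so an
off-diagonal misprint cannot distort them.

## The synthetic generator

The study's raw recordings are not publicly deposited, so the package
includes a generator that emulates the *statistical structure* the
analysis relies on, making every downstream stage testable end to end.

Each muscle's stance activation is a sum of Gaussian bursts in normalized
stance time (e.g. quadriceps and hamstrings loaded early, plantarflexors
peaking near 70 % of stance at push-off). Environments act on these
shapes through per-muscle amplitude multipliers and burst-center shifts,
scaled by a `separation` parameter: at separation 0 all five environments
are identical (classification must sit at chance); at the default 1 the
effects apply in full. The largest effects are deliberately placed on the
ankle plantarflexors — push-off demand differs most across terrains, which
is also the biomechanical reason the real analysis found MG/LG/Sol most
informative — while EDL barely changes, making it the least informative
channel by construction. These choices make the qualitative
muscle-importance ranking reproducible; they do not (and cannot) encode
the study's exact percentages.

The raw sEMG signal is the envelope multiplied by a unit-variance Gaussian
carrier band-limited to 20–450 Hz — inside the 20–500 Hz analysis band and
below Nyquist at 1200 Hz — so the band-pass is nearly transparent and the
rectify → low-pass chain demodulates the envelope back up to the
half-normal factor $\sqrt{2/\pi}$, which the flat-ground normalization
cancels. The vGRF is a smooth double-bump curve (loading peak ≈ 1.15 body
weight, push-off ≈ 1.05, valley ≈ 0.75) with exact zeros in the swing pads
and a sharp onset ramp, so the 20 N crossing lands within a sample or two
of the constructed stance start.

Variability not constrained by any published figure was set once at
values typical for gait data: subject stance durations uniform on
0.6–0.9 s with 4 % log-normal trial jitter; per-muscle subject gains
log-normal (sd 0.25, removed by normalization); per-trial global and
per-muscle amplitude jitter log-normal (sd 0.08 and 0.12); burst-center
jitter sd 0.015 of stance; resting noise floor 8 % of the unit burst.
All randomness derives from
(master seed, subject, environment, trial, channel) through a fixed
key-derivation rule, so any single trial is regenerable in isolation and
reruns are byte-identical.

What the generator does *not* emulate: motor-unit physiology, electrode
crosstalk, movement artefacts, fatigue drift, kinematic variability, or
male/female differences. Passing tests on synthetic data therefore
demonstrate that the pipeline's machinery is correct and calibrated, not
that real five-terrain sEMG is this separable; the published accuracies
are reproduced from the published matrices, not re-derived from signals.

## Numerical choices and degenerate inputs

* Zero-phase filtering via `signal::filtfilt`; the DC-rejection,
  pass-band-unity and stop-band checks in the test suite pin its
  behaviour.
* `timeNormalize()` is exact on linear input and the identity on a
  1000-point grid; inputs shorter than 2 samples are errors.
* Degenerate normalization references (zero or non-finite flat-ground
  peaks) are errors naming subject and muscle, never silent division.
* `countsFromPercent()` requires each cell to be within 0.5 count of an
  integer and (by default) each row to sum to the declared per-row count.
* Degenerate one-vs-rest denominators yield `NA`, not 0.
* All classed errors (`GaitEnvNoStance`, `GaitEnvDivergence`, …) are
  testable conditions.

## Problem sizes used in the checks

The default study shape — 27 subjects × 5 environments × 5 trials = 675
trials, 135 per environment, 108/27 train/test per class — is used for the
full-scale acceptance properties (all-muscle accuracy ≥ 90 %, ankle
extensors outranking EDL, label-shuffled accuracy inside the 12–28 %
binomial chance band at n = 135). Unit and property tests use a 4-subject,
3-trial miniature of the same design, which exercises every code path in
seconds.

## Known limitations

* The published results cannot be re-derived from raw data (none are
  deposited); the worked-example surface is exact reproduction from the
  published matrices, and the synthetic surface is property-based.
* Hidden width, learning rate, epochs and the subject-separation question
  for the 80/20 split are unknown in the source; defaults are documented
  choices, not recovered values.
* Trial-level splitting leaks subject identity; subject-wise mode is
  provided but changes the task difficulty.
* No terrain-transition detection: profiles are whole-stance, single
  terrain. Online/streaming classification is out of scope.
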