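---
title: "Predicting visuomotor learning state from pre-trial EEG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting visuomotor learning state from pre-trial EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vmil)
```

## The question and the analysis

During visuomotor learning, performance on a reaching task improves from
trial to trial. The per-trial performance measure used throughout this
package is the normalized time-to-target (TTT): the movement duration
from the go cue to target contact divided by the start-to-target distance,
in s/m. The analysis asks whether the *slow component* of that learning
trajectory can be read out from EEG recorded *before* each movement —
during a 5 s pre-trial baseline or a 2.5–4 s movement-planning phase —
and, if so, which cortical sources and frequency bands carry the
information.

The chain is:

1. **Synthetic cohort** — multi-subject EEG sessions with a known latent
   learning curve that jointly drives TTT and the alpha/mu-band power of
   designated sources (the recovery target for everything downstream).
2. **Preprocessing** — common average reference; 3 Hz third-order
   Butterworth high-pass (zero-phase) for the decomposition; pooling all
   subjects and reduction to principal components.
3. **SOBI** — second-order blind identification: joint approximate
   diagonalization of time-lagged covariance matrices of the whitened
   pooled signal, then automated artifact-component rejection.
4. **Features** — per-trial log-bandpower of each kept component in five
   bands (delta 0.1–4, theta 4–7, alpha/mu 8–14, beta 20–30, gamma
   55–85 Hz), low-pass filtered across trials at 0.1 radians/trial.
5. **Prediction** — a regression forest trained on all-but-one subject
   predicts the held-out subject's filtered TTT
   (leave-one-subject-out CV).
6. **Evaluation** — the modified coefficient of determination
   `R²_mod(x, y) = R²(x, y) / R²(x, LP(x, c))` and a group-level
   permutation test over trial orderings.
7. **Interpretation** — out-of-bag permutation variable importance and
   value-substitution influence curves per (component, band) variable.

## The statistic

Because the regression target is low-pass filtered across trials, a
perfect band-limited prediction cannot reach an ordinary R² of 1 against
the raw series. `r2_mod()` therefore rescales R² by the R² that the
low-pass-filtered observed series itself achieves:
`R²(x, LP(x, c))` is the ceiling for any model confined to trial
frequencies below `c`, so `R²_mod` ranges over (−∞, 1]: 1 means all
explainable slow variance explained, 0 a prediction no better than the
mean, negative values mean variance was added. The cut-off `c = 0.1`
radians per trial is chosen where the TTT periodograms (`ttt_psd()`)
concentrate their mass; `0.1` rad/trial ≈ 0.016 cycles/trial, i.e.
fluctuations slower than ~60 trials per cycle.

The group-level test permutes each subject's observed trial order
independently, recomputes `R²_mod` per subject against the fixed
predictions, and aggregates (mean by default; the median is also
reported). The p-value uses the add-one estimator
`(1 + #{draws ≥ observed}) / (1 + n_perm)`, so it can never be exactly
zero; with 10,000 draws the smallest attainable value is ~1e-4.
Permuting usually destroys the slow structure that the denominator
`R²(x_perm, LP(x_perm, c))` measures; when a permuted denominator is not
positive, that subject's draw contributes 0 ("no explainable slow
variance ⇒ no credit") — a convention the statistic itself does not
dictate, chosen so that degenerate draws neither explode the ratio nor
abort the test. The alternative of reusing the unpermuted denominator is
available via `recompute_denominator = FALSE`.

## The synthetic cohort

`sim_config()` defaults describe the emulated experiment: 6 subjects,
200 trials in four 50-trial blocks with one-minute intermissions, trial
phases of 5 s baseline, 2.5–4 s planning (uniform), a go phase capped at
10 s, and a 1.5–3 s return. Observed TTT follows
`asymptote + (initial − asymptote)·exp(−(t−1)/decay)` plus i.i.d.
Gaussian noise (defaults 25 → 8 s/m, decay 50 trials, sd 3 s/m — an
exponential is the conventional single-process learning model, and its
parameters are recoverable). TTT is floored at 0.5 s/m; faster reaches
are not physiologically plausible and the floor keeps movement durations
positive. Reaches that would exceed the 10 s limit are recorded as
timeouts carrying the full limit duration, as the behavioral convention
dictates.

Each of 16 sources is unit-variance band-limited noise in a labeled band
superposed on a 1/f background (exponent 1, sd 1 µV). Sources sharing a
band split it into adjacent sub-bands — distinct peak frequencies, as
cortical rhythms across regions have. This matters structurally, not
cosmetically: sources with identical spectra have proportional lagged
covariances and are therefore invisible to any second-order separation
method; a generator without spectral diversity poses SOBI an unsolvable
problem. Channels are an
instantaneous linear mixture (32 channels; columns unit-norm; per-subject
5% Gaussian jitter standing in for anatomical variability) plus sensor
noise (sd 0.5 µV). For informative sources, the band-limited amplitude is
`exp(sign · strength · (latent − ½))` per trial — constant within a
trial, because all downstream features are per-trial scalars. The default
has three informative alpha/mu sources with `sign = −1`: more alpha/mu
power goes with faster movements, the direction reported for sensorimotor
rhythms.

Desk-scale defaults (250 Hz, 32 channels, 16 sources) keep a full cohort
run in minutes on one CPU; the emulated study's dimensions (1 kHz, ~120
channels, 64 components) remain reachable through the config. What the
generator deliberately does *not* emulate: realistic head-model forward
physics, eye/muscle artifacts beyond one optional broadband test source,
per-subject differences in learning-curve shape, and nonstationarity of
the mixing over the session. Passing tests therefore demonstrate that the
pipeline recovers what its own generative assumptions plant — not that
real EEG contains such signals.

### Coupling-strength calibration

The emulated study reports per-subject R²_mod between roughly 0 and 0.45;
no quantitative effect size for the alpha/mu–performance coupling is
available from it. The default `strength = 0.25` was therefore
calibrated — a documented calibration, not ground truth: a sweep over
{0.1, 0.15, 0.2, 0.25} of the full default pipeline showed the group
median R²_mod rising from −0.20 through 0.33, and the default was fixed
at the value that keeps the median inside the reported range with the
per-subject spread (−0.08 to 0.61 at the calibration seed) resembling
the reported heterogeneity. At strengths near 1 the synthetic cohort is
far cleaner than human EEG and R²_mod saturates toward 1.

## Numerical choices

- **Zero-phase filtering.** All Butterworth filters are applied
  forward–backward (doubling the effective order) to avoid phase
  distortion of epochs; the filter recursion uses steady-state initial
  conditions, so constant series pass through exactly. The trial-domain
  low-pass uses mirror (even-reflection) padding of 24 samples: odd
  reflection — the textbook choice for trending series — pins a
  zero-phase filter's output to the raw values at the series ends, so
  the first and last trials would escape smoothing entirely; with
  mirror padding every trial is genuinely smoothed, at the cost of a
  flattened local slope at the ends. The continuous high-pass pads by
  three time constants of its cut-off (odd reflection, where pinning is
  irrelevant and trend preservation matters).
- **Planning epochs** are the first 2.5 s after planning onset — the
  guaranteed minimum planning duration — so epochs are equal length.
- **PCA** is computed on mean-centered pooled data; scores are whitened
  because joint diagonalization assumes an identity lag-0 covariance.
  With synthetic fixtures the component count defaults to the generator's
  source count; 64 is the faithful choice for ~120-channel input.
- **Bandpower** uses a Hann window over the full epoch, one FFT, power
  summed over bins in [lower, upper), natural log, with a 1e-12 power
  floor against degenerate epochs. Features are computed on minimally
  (0.1 Hz) high-passed data rather than the 3 Hz-filtered decomposition
  input, otherwise the delta band (0.1–4 Hz) would be empty; the
  decomposition itself is always trained on 3 Hz-filtered data. This is a
  deliberate reading of an ambiguity in the emulated procedure.
- **SOBI** uses lags 1–50 samples (4–200 ms at 250 Hz, common practice),
  rotation-angle tolerance 1e-8, at most 200 sweeps. Component order
  (decreasing lagged-autocovariance energy) and sign (largest topography
  weight positive) are fixed conventions for reproducibility only.
- **Artifact rejection** replaces visual inspection with three criteria:
  3–40 Hz spectral slope outside [−10, −0.2] log-power per log-Hz, more
  than 50% of power above 40 Hz, or a topography with one channel holding
  more than 80% of squared weight. On synthetic data these keep planted
  cortical sources and reject the broadband single-channel artifact
  source; the emulated study kept 14 of 64 components, a count this
  package does not target.
- **Targets.** TTT is z-scored within subject, then low-pass filtered at
  `c` for training; predictions are scored against the *unfiltered*
  z-scored series via `r2_mod()`, whose denominator absorbs the
  band-limitation. Whether the emulated analysis filtered its training
  targets is unstated; this choice is consistent with the statistic's
  denominator logic, and raw-target training is available via
  `filter_target = FALSE`.
- **Forest defaults**: 500 trees, `mtry = ⌈p/3⌉` (regression convention),
  minimum node size 5, bootstrap resampling — the emulated study reports
  no hyperparameters. It says "classifier" but predicts a continuous
  quantity; this is a regression forest throughout. Fold seeds derive
  from the forest specification's seed and the fold index only, so no
  fold depends on another fold's data.
- **Importance** is computed from per-tree out-of-bag rows (Breiman's
  formulation), averaged over `n_repeats` permutations (default 10; the
  pipeline uses 3 — at 70+ variables × 6 folds the extra repeats change
  fold rankings by little while tripling this stage's cost). It is
  reported in target-variance units, unnormalized, with per-fold ranks
  for cross-fold comparison.
- **Influence curves** use a 50-point grid spanning the variable's
  training range ("a sufficiently sized subset of the range"); values
  outside it saturate trees anyway.

## The test's level under a smooth null

`null_calibration()` measures how often the permutation test rejects
when features carry no information: each replicate draws per-subject
learning-curve TTT and feature tables of trial-domain-smoothed noise
(the same 0.1 rad/trial smoothing the real pipeline applies to
bandpowers, with zero behavioral coupling), runs leave-one-subject-out
prediction and the permutation test. The sensor-to-SOBI chain is
bypassed: once features are uninformative, the upstream signal
processing cannot alter the test's level, and running hundreds of full
EEG pipelines would multiply the cost a hundredfold for no additional
evidence.

What the measurement shows is important to understand before trusting
small p-values from this design: the test is **anti-conservative under
a smooth null**. Because features are low-pass filtered across trials,
null predictions are themselves smooth paths with an effective sample
size of only ~6 per 200-trial series, while the observed TTT carries a
monotone learning trend; permuting trial order destroys both kinds of
structure. The observed statistic therefore has several times the
spread of the permutation distribution even when predictions are
independent of behavior — under the default convention (denominator
recomputed on the permuted series, subject draws floored at 0 when it
is non-positive) the permuted denominators shrink toward zero and the
observed value beats essentially every draw. Reusing the unpermuted
denominator (`recompute_denominator = FALSE`) removes the ratio
artifact but leaves the spurious smooth-smooth correlation, with null
p-values piling up near 0 and 1. No convention within the test's
definition restores the nominal level; a structure-preserving null
(block permutation or phase randomization) would be required, and is
outside this package's scope. Rejections of the null on data generated
*with* coupling remain meaningful in direction and magnitude of
`R²_mod`, but the nominal p-value overstates the evidence, and the
shipped calibration check reports the measured rejection rate rather
than hiding it.

## Problem sizes used in the shipped checks

The acceptance-style checks run the full default cohort (6 × 200 trials,
250 Hz, 32 channels, 10,000 permutations) once — minutes on one CPU —
and desk-scale variants (3 × 80 trials) elsewhere; the calibration uses
50 feature-level replicates. These sizes are the package's choice of a
desk-scale analog: large enough for every stage to operate in its
intended regime, small enough to re-run routinely.

## Known limitations

- Blind separation is only defined up to permutation and sign; all
  component-level statements are made after matching topographies to the
  generator's mixing (`match_sources()`), which is itself imperfect at
  realistic noise levels.
- The group permutation test conditions on the fixed predictions; its
  exchange-invariance over subjects is exact only up to the per-subject
  permutation streams.
- With a shared learning-curve shape across subjects, cross-subject
  transfer is easier than in human cohorts (where prior experience and
  fatigue produce outlying subjects); synthetic R²_mod values are
  correspondingly homogeneous.
- The delta band on 2.5 s planning epochs rests on few FFT bins; its
  features are noisy by construction.
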