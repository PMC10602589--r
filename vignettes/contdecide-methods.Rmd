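---
title: "Continuous decision-making: models and methods in contdecide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous decision-making: models and methods in contdecide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contdecide)
```

## The task and what the package computes

`contdecide` implements an analysis pipeline for continuous perceptual
decision-making with a random-dot-kinematogram stimulus. Instead of discrete
trials, observers monitor a single evidence stream for five minutes at a
time. The stream's signed motion coherence (between -1, all dots leftward,
and +1, all rightward) is piecewise constant: it is resampled at
exponentially distributed intervals, so the stimulus is a dense sequence of
"jump events". During *baseline periods* the generating mean is zero;
during embedded *response periods* the mean steps to one of
{±0.3, ±0.4, ±0.5} and the observer should report the direction with a
left/right buttonpress. Correct reports earn +3 points, direction errors
-3, and missed periods and false alarms -1.5 each. Because response-period
onsets are never cued, the only viable strategy is temporally extended,
recency-weighted (leaky) integration of the coherence stream.

The pipeline has five parts: stimulus simulation and scoring
(`generate_block()`, `score_responses()`), reverse-correlation behavioural
analysis (`compute_integration_kernel()`, `fit_exponential_kernel()`,
`detection_summary()`), an Ornstein-Uhlenbeck accumulator agent and its
reward landscape (`simulate_ou_block()`, `grid_search_ou()`,
`model_kernel_sweep()`), deconvolutional estimation of temporal response
functions from continuous recordings (`build_design_matrix()`,
`fit_trf()`, `simulate_eeg()`), and group-level statistics
(`paired_cluster_permutation()`, `across_subject_correlation()`).

## Stimulus generation

Noise-interval durations follow an exponential distribution with mean
270 ms, truncated to [10, 1000] ms. Truncation is by *rejection
resampling* — out-of-range draws are redrawn — which preserves the
exponential shape within the bounds; clipping draws to the bounds would
place probability mass atop them and is deliberately not used. Under this
density the mean accepted duration is ≈ 254 ms, so a 300-s block contains
≈ 1180 intervals. Per interval, one coherence value is drawn from a normal
distribution whose mean and SD depend on the period label *at the
interval's onset* (baseline: mean 0, SD 0.5; response: period mean,
SD 0.3); values beyond ±1 are set to ±1. Interval tiling is independent of
the period schedule, so intervals may straddle period boundaries carrying
their onset label — a deliberate simplification that matches how the
stimulus stream is constructed frame by frame.

The period schedule alternates baseline and response periods. Four
environments form a 2 × 2 design: response periods are LONG (5 s) or
SHORT (3 s), and FREQUENT (baseline durations uniform on 3–8 s) or RARE
(uniform on 5–40 s). Only a range is stated for baseline durations, so the
uniform distribution over that range is used. The final period is clipped
at the block end; a trailing response period is kept only if at least one
10-ms sample of it fits.

Time is materialised on a 100-Hz grid; interval onsets are rounded to the
nearest sample for the per-sample series while unrounded onsets are kept
in the interval table. One root seed is split deterministically into
independent sub-streams for the schedule, the interval durations and the
coherence draws, so a block is bit-reproducible from
`(condition, config, seed)` and two conditions sharing a seed differ only
through their schedules.

### Scoring

A press during a response period is scored against that period if no
earlier press claimed it; direction is compared with the sign of the
period's mean. A press within 500 ms *after* a period's nominal end is
still credited (compensating non-decision time), again only for unclaimed
periods. Everything else is a false alarm. Correct and incorrect presses
terminate the period immediately: its `actual_end_s` becomes the press
time and the remaining scheduled time counts as baseline. Scheduled period
boundaries themselves never move — an early termination extends the
following baseline rather than shifting later periods, which keeps scoring
well-defined on a fixed schedule and keeps simulated agents comparable
across parameter settings on the same stream. Total points are exactly
`3·nCorrect − 3·nIncorrect − 1.5·(nFalseAlarm + nMiss)`.

## Integration kernels

Reverse correlation recovers the evidence weighting empirically: the
signed coherence over the 5 s preceding each buttonpress (sign-flipped for
leftward presses) is averaged across events on a 10-ms lag grid
(501 points). Presses within 5 s of a block start are excluded rather than
zero-padded. For correct-response kernels, LONG-condition responses slower
than 3.5 s are excluded so LONG and SHORT remain comparable; false-alarm
kernels have no such cut, since a false alarm has no period onset.

The kernel decay is summarised by `k(t) = A e^{-t/τ}`, where `t` is time
before the kernel peak, `A` the peak amplitude (fraction of dots toward
the chosen direction) and `τ` the decay constant in seconds. The peak is
the global argmax of the kernel, ties broken toward the lag nearest the
response. The fit minimises the least-squares cost over all lags up to and
including the peak plus an L2 penalty `0.01 (A² + τ²)`, by Nelder–Mead
simplex search on log-parameters (enforcing positivity), initialised at
`A₀ = kernel maximum`, `τ₀ = 1 s`, with objective tolerance 1e-8.
`R² = 1 − RSS/TSS` is computed on the fitted range without the penalty,
with TSS about the fitted-range mean. Constant kernels, optimiser failure,
or divergent `τ` set a `degenerate` flag. Unit tests verify the optimiser
against a dense two-dimensional grid search of the same objective and show
median relative error of `τ̂` below 10% for kernels with `A ∈ [0.2, 0.6]`,
`τ ∈ [0.3, 2]` s and additive noise of SD 0.02.

## The leaky accumulator

The agent is an Ornstein–Uhlenbeck process on the stimulus grid:

    X_t = (1 + λ) X_{t−1} + g M_t + ε_t,   ε_t ~ N(0, σ²)

with `M_t` the signed momentary coherence, `λ ∈ [−1, 0]` the leak, and a
response emitted whenever `|X| ≥ θ` (direction = sign of `X`), after which
`X` resets to zero. With `λ = 0` the update is drift-diffusion (perfect)
accumulation. The integration step is one stimulus sample (10 ms), so `λ`
and `σ` are per-10-ms quantities. There is no non-decision time and no
time-varying urgency. Simulation is closed-loop: when a press claims a
running response period the stimulus reverts to baseline statistics for
the remainder of that period, exactly as the task does for human
observers, and the emitted presses are scored by the same
`score_responses()` path as human logs.

### Defaults for gain, noise and the search grids

`g` is held at 1 (only the ratio of signal to `θ` and `σ` matters). The
accumulator noise default is `σ = 2` per step. This value encodes the
assumption that internal sensory noise per 10-ms sample is several times
the momentary evidence (|M| ≤ 1): only then is detecting a 30–50%
coherence shift over seconds of integration genuinely hard. With much
smaller `σ`, the reward-optimal agent detects essentially every response
period while emitting almost no false alarms — behaviour far better than
human observers achieve on this stimulus — and the environment
manipulations have nothing to trade off against. At `σ = 2` the optimal
agent's detection rates and false-alarm rates fall in the empirically
plausible range (roughly 50–90% detection, a few false alarms per minute),
and the reward landscape shows the characteristic ridge along which a
stronger leak trades off against a lower threshold.

The default search grids are log-spaced: leak magnitudes from 5·10⁻⁴ to
0.02 per step (integration timescales of roughly 0.5–20 s) plus the
diffusion limit `λ = 0`, and thresholds from 30 to 400 accumulator units
(the scale of evidence accumulated over a response period). On these axes
the landscape has an interior optimum; linear axes spanning strong leaks
put every cell in a regime where the agent cannot earn points. The
top-decile mask marks the best 10% of cells of the mean landscape.

`model_kernel_sweep()` applies the behavioural kernel analysis to the
agent's own false alarms: sweeping `θ` at fixed `λ` makes the fitted `τ̂`
rise monotonically (a higher threshold demands temporally sustained
evidence), while sweeping `λ` at fixed `θ` mainly moves the amplitude
`Â` — the signature that threshold, not leak, controls the recovered decay
constant. Settings yielding fewer than 50 false alarms are flagged
under-sampled and their fits should not be interpreted.

## Deconvolutional TRF estimation

Continuous recordings are modelled with eleven regressors: jump-event
sticks with parametric modulators for the new absolute coherence
(`jump_level`) and the absolute coherence change (`jump_abs_delta`); the
continuous absolute and signed momentary evidence; response-period onset
sticks and their |coherence| modulator; and correct/false-alarm
buttonpress sticks with signed (+1 right / −1 left) twins. Each regressor
is time-expanded ("staircased") into one column per 10-ms lag over its
window: 1000 ms pre / 1500 ms post for the jump sticks and level (251
columns), 1500/1500 for |Δevidence| and the continuous regressors (301),
5000/3500 for buttonpresses and 500/8000 for response-period regressors
(851). A column at lag ℓ ≥ 0 models activity ℓ ms *after* the event
(negative lags are anticipatory); lagged copies are zero-padded at block
edges, never wrapped.

Design choices the source conventions leave open, fixed here:

* Evidence-derived regressors (the first five) are estimated from baseline
  periods only; this is implemented by zeroing their values outside
  baseline samples before time expansion (samples after an early
  termination count as baseline). The buttonpress and period-onset
  regressors span the whole block.
* Parametric modulators are *not* mean-centred (switchable via the raw
  streams if desired).
* The first interval's `jump_abs_delta` is referenced against coherence 0.

Estimation is ordinary least squares per channel on the valid rows,
`β̂ = pinv(X) Y`, via Cholesky on the normal equations when the design has
full column rank and a minimum-norm eigendecomposition pseudoinverse (with
a warning) otherwise. The design matrix is stored sparsely. For real
recordings, rows within ±500 ms of any |sample| ≥ 100 µV would be masked;
for synthetic data the mask is user-supplied. The package performs no
filtering, re-referencing or other pre-processing — ingestion expects a
continuous numeric matrix aligned to the stimulus grid.

`simulate_eeg()` builds synthetic recordings by direct convolution of
each regressor stream with a known ground-truth curve (plus white or AR(1)
noise), deliberately *not* through the design matrix, so round-trip
recovery tests exercise two independent code paths. `triphasic_curve()`
supplies the three-lobed, final-negative shape used for the continuous
|evidence| response. At the default SNR (curve amplitudes of order 1,
AR(1) noise with marginal SD 1 and coefficient 0.9) a 300-s block recovers
the triphasic curve with r > 0.95.

`regressor_collinearity()` reports squared correlations between the four
evidence regressors over baseline data. Pairs of stick regressors are
compared at the *event level* (their values at jump samples): comparing
full series would measure only their shared support. Pairs involving the
continuous regressor are compared sample by sample. Under this convention
the squared correlation between `jump_level` (= |new|) and
`jump_abs_delta` (= |new − old|) has a closed-form benchmark for untruncated
normals — `corr(|A|, |A−B|)² ≈ 0.21` via the bivariate-normal
absolute-moment formula with `corr(A, A−B) = 1/√2` — and the ±1 truncation
pulls the measured value down to ≈ 0.18. Event-level comparisons against
the constant `jump_event` stick have zero variance and are flagged
undefined rather than reported as 0.

## Group statistics

Beta timecourses are smoothed with a unit-area Gaussian kernel of 75 ms
FWHM (SD = FWHM / (2√(2 ln 2)) samples), with reflective edge handling so
constants pass through unchanged.

The paired cluster permutation test computes a per-timepoint paired t
across subjects, forms clusters from contiguous runs with |t| above the
cluster-forming threshold (default 2.07), and scores each cluster by its
summed t ("mass"; extent-based scoring is a near-equivalent alternative —
mass is used because it weights both strength and duration). The null
distribution of the maximal absolute cluster mass comes from random
sign-flips of each subject's difference curve — the standard exchange for
paired designs — with full enumeration whenever 2ⁿ does not exceed the
requested permutation count. The observed labelling is included in the
null, so p ≥ 1/(n_perm + 1). Two-tailed inference clusters |t| with the
sign recorded. Electrode selection and averaging happen upstream; the test
operates on channel-averaged curves. Calibration runs (24 synthetic
subjects, 500 null simulations) put the family-wise error within
Monte-Carlo error of the nominal 0.05.

`across_subject_correlation()` relates a per-subject behavioural scalar
(typically the kernel decay constant τ) to smoothed beta curves via
Spearman rank correlation at each timepoint, plus a summary correlation of
window-averaged betas (default window 420–750 ms, where the late negative
lobe of the triphasic evidence response sits). Ties get average ranks;
across-subject-constant inputs are flagged undefined, not coerced to a
number.

## What the synthetic data does and does not emulate

The generator reproduces the stimulus *statistics* — interval durations,
Gaussian coherence samples with condition-dependent scheduling, the
scoring rule — and, for recordings, linear convolution of known response
functions with those stimulus streams plus stationary noise. It does not
render dots (no dot density, speed or display geometry), does not model a
second decision-irrelevant motion stream (though the block structure does
not preclude adding one), and produces no physiological artifacts:
real-EEG nuisance structure (eyeblinks, drifts, filtering effects,
re-referencing) is absent. Passing recovery tests therefore demonstrate
correctness of the estimators under the stated noise models, not
robustness to un-modelled recording artifacts. The accumulator is likewise
a normative probe of the task, not a fitted model of any participant:
fitting λ and θ to human logs is out of scope.

## Problem sizes and numerical notes

The shipped tests run the full pipeline at the sizes the analyses need to
be stable while staying quick: 100 seeded blocks for stimulus-density
checks, a single 300-s block (≈ 15 000 baseline-masked rows × 1104
columns) for TRF round trips, 100 synthetic kernels for the fit-recovery
study, 10 blocks per setting for the model-kernel sweeps, 20 blocks per
condition on the default 12 × 12 grid for the reward-landscape
comparisons, and 500 null simulations for permutation-test calibration.
Threshold crossings use a relative tolerance of 1e-12 so that exact
arithmetic cases (e.g. ten 0.1-steps reaching θ = 1) behave as intended
despite floating-point accumulation. All randomness flows through
explicit seeds; a root seed is split into per-component sub-seeds with a
fixed integer recurrence, keeping every derived seed below 2³¹.

## Known limitations

* The accumulator's absolute parameter scales (σ, θ, and hence the grid
  axes) are tied to the 10-ms step convention; they are not comparable
  across step sizes without rescaling.
* The per-block argmax of the reward landscape is a noisy statistic on a
  flat trade-off ridge; condition effects on (λ*, θ*) are ordinal,
  majority-of-blocks properties, not point estimates.
* Only temporal (channel-averaged) clustering is provided, not
  spatio-temporal clustering over channels.
* The collinearity table's conventions are one reasonable resolution of an
  under-specified computation; its 0.18 benchmark is approximate by
  construction.
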