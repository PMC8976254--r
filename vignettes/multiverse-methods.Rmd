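---
title: "From sensor streams to sleep features to a multiverse of models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From sensor streams to sleep features to a multiverse of models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepverse)
```

## The problem

Smartphones passively record signals that plausibly track sleep: the phone
stops moving, gets plugged in, the room goes dark, the screen stays off,
Wi-Fi stays connected.  Turning those event streams into nightly sleep
features, and those features into predictions of morning sleep quality
(SSQ), daily negative affect (NA) and depression, requires dozens of
seemingly arbitrary analysis choices.  This package implements that
pipeline as a *multiverse*: every defensible combination of sensor rule,
feature, outcome, model family, outlier strategy and run-length parameter
is enumerated (12,600 combinations under the defaults) and evaluated under
a hold-out workflow, so that conclusions can be judged by their robustness
across choices rather than by one arbitrary path.

Because no participant-level dataset is available, the package ships a
synthetic-study generator with known ground truth; every downstream stage
is testable by construction and by parameter recovery.

## Sleep classification and the night grid

Six sensors each carry a per-instant sleep rule: |centred accelerometer| <
{0.25, 0.5, 1} m/s^2; battery charging; illuminance < {8, 12, 16} lux;
activity recognition returning "Still"; screen off; Wi-Fi connected.  The
threshold variants give ten *sensor configurations*.  Thresholds are
strict ("less than"), so 8 lux at the 8-lux threshold counts as awake.

Cleaning precedes classification: per participant-sensor streams with
fewer than 10 observations or all-zero values are excluded (with a
reported reason); temporally isolated events are removed by a boxplot rule
on each event's min-neighbour gap (gap > Q3 + 1.5 IQR); accelerometer
values are centred per participant and replaced by absolute values
(emulating uncalibrated sensors); and screen interactions shorter than
12 s are deleted after collapsing duplicate states, removing notification
flashes before they can vote.

A night covers 10 PM-10 AM in 144 five-minute windows.  Each window takes
the majority state of its observations; ties inherit the previous window's
resolved state (a first-window tie stays missing); empty windows are
missing, except for the state-machine sensors (screen, charging, Wi-Fi)
where the last emitted state contributes one implied observation.
Missing windows after the first observed one are filled by
last-observation-carried-forward.

## Features

Bed time is the first window opening a run of at least k consecutive
sleeping windows (k in 3-5, one multiverse axis shared with wake
detection).  Wake-up time is the start of the *terminal* awake run (>= k)
that extends to the end of the night; a qualifying awake run that is
followed by more sleep is an interruption, not the wake-up.  We chose the
terminal-run reading because the alternative ("first awake run after bed")
would let any long interruption end the night, contradicting the intended
picture of interruptions lying inside the sleep interval.  When the night
never ends in such a run (sleeping through 10 AM) the wake-up is missing -
a frequent, expected outcome.

From bed (B) and wake (W) windows: SleepTime = (W - B) x 5 min; the
interruptions are the maximal awake runs strictly inside (B, W), counted
(nInterruptions) and totalled x 5 min (InterruptionsDuration); TotalSleep
counts all sleeping windows in the whole night regardless of B/W;
devAvgBedTime and devAvgWakeUpTime are signed deviations (hours) from the
participant's mean on the recentred night axis (10 PM = 0, ..., 10 AM =
12), using all available nights; UserActive is the minutes spent walking
or cycling between 10 AM and 10 PM of the previous day, read off the
activity stream as a state machine (an episode runs from an active label
to the next differing label; trailing episodes close at 10 PM).

## Outlier strategies

Four strategies, applied to the feature values before modelling: keep
everything; per participant, keep values within 3 sample SDs of the
median; within 3 *unscaled* MADs of the median (no 1.4826 factor - the
rule is literal); or a pooled multivariate isolation forest over all seven
features with contamination 0.05 and a fixed seed.  A zero MAD keeps only
exact-median values, loudly.  Participants with fewer than 3 values pass
unfiltered (dispersion undefined).  Rows with missing features cannot be
scored by the forest and are never removed by it.  For depression the
per-participant median rules are degenerate (one row per participant after
aggregation), so outlier handling operates on the nightly rows before
aggregating participant means.

## Models and evaluation

One input feature per model.  Five families: a random-intercept mixed
model (the slope is reported for the feature standardized on training
statistics), k-nearest neighbours (k in {3,5,7,9,15}), a radial-kernel SVM
in its least-squares form (kernel ridge with median-heuristic bandwidth,
cost in {0.25,1,4}), gradient-boosted trees (depth {2,3}, 100 trees,
learning rate 0.1, compiled in C++), and a spline GAM.  For depression,
which has no nested structure, the mixed model is replaced by a linear
model.  Hyperparameters are tuned by an internal seeded 5-fold CV on the
training set only.  With one predictor a spline GAM coincides with a
smoothing spline, so the family is backed by `stats::smooth.spline` with
an equivalent-df grid {5,10}; below 4 distinct feature values it
degenerates to a linear fit.

Performance is predicted R^2 on held-out data, `1 - SSE/SST` with SST
about the *evaluation-set* mean; it is negative when predictions are worse
than that mean.  The longitudinal split follows each participant's own
study clock: days 1-7 train, 8-11 validation, 12-14 test.  Depression uses
a participant-level 60/20/20 split stratified by gender with
largest-remainder rounding.

For each outcome, models within one standard error of the best validation
R^2 are selected (at most five; ties prefer the simpler family).  The "1
SE" is deliberately isolated in `bootstrap_r2_se()`: a seeded
nonparametric bootstrap (1,000 resamples) over the best model's validation
(observed, predicted) pairs, because no operational definition is fixed by
convention; alternatives (SE across folds or across configurations) can be
swapped in at that single point.  Selected models are refitted on the
training rows only - never on validation or test - and finally scored on
the test set.

## The synthetic world

`sim_params()` states the world: 50 participants x 14 nights; bed times
around 11:30 PM (SD 45 min), wake times around 7:30 AM, clipped into the
10 PM-10 AM night; Poisson(1) nightly interruptions of 5-30 min; event
streams as renewal processes with normal(2.9, 6.72)-minute intervals
truncated to (0.1, 15] so no gap exceeds 15 minutes (the reported mean/SD
parameterize the underlying normal, not the truncated moments); a
per-participant accelerometer offset (SD 0.3 m/s^2) that centring must
undo; 2% of samples flipped to the opposite state's value distribution;
Poisson(2) sub-12-second screen flashes per night; 30% of morning SSQ
beeps missed; gender 72% female.  During true sleep every sensor satisfies
its rule at the strictest threshold; awake samples violate it at the most
lenient one, so with flips and flashes disabled the pipeline must recover
the schedule up to sampling-gap resolution.

Outcomes are linear in the *mean-centred* true features plus a participant
random intercept (SD 8 for SSQ/NA) and residual noise (SD 10), clipped to
[0, 100]; centring keeps the baseline (50) at the outcome's population
mean so clipping stays a rare boundary guard rather than a source of slope
bias.  The night between day d-1 and d pairs with day d's morning SSQ and
day d's NA.  Depression is one value per participant, linear in
participant-mean features.

What the generator does *not* emulate - circadian drift, weekday
structure, device heterogeneity, correlated sensor failures - bounds what
a green test establishes: the pipeline recovers the stated world, not any
particular real population.

## Numerical choices and degenerate inputs

Ties in the majority vote inherit the previous window (the carry-forward
philosophy); a first-window tie is missing.  Windows are half-open
[t, t + 5 min).  Gap outliers use quantile type 7 and the 1.5 IQR whisker.
Streams under 4 events skip gap filtering (quartiles undefined) with a
warning.  Mixed-model non-convergence, degenerate predictors (< 2 distinct
values) and empty per-config row sets are recorded as `inoperable`
results, never sweep failures.  All stochastic components (fold
assignment, boosting, isolation forest, bootstrap, splits) derive child
seeds from one user seed, so sweeps are reproducible and
order-independent.

A note on idempotence: the removal passes (sparse/dead streams, screen
flashes) are idempotent; centring-then-absolute-value and the gap rule are
single-pass operations by definition (|x - mean(x)| applied twice is a
different map), matching the one-shot preprocessing they emulate.

## Known limitations

The per-night grid treats the 10 PM-10 AM window as the only candidate
sleep period; naps and shifted schedules are invisible.  The 1-SE rule
depends on a bootstrap definition the source procedure left open.  The
isolation forest is pooled across participants, so a participant with
genuinely unusual sleep can lose rows.  Wake-up detection fails by design
when a night ends asleep, which concentrates missingness in late-sleeping
participants - mirrored in the generator only through the night boundary,
not through any behavioural mechanism.
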