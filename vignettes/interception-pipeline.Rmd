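---
title: "Methods: simulating and analysing eye-hand interception with target jumps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing eye-hand interception with target jumps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jumptrack)
```

## The task and its geometry

`jumptrack` models a rapid manual interception task. A circular target
(radius 0.5 cm) appears 22 cm above the centre of a start area on a vertical
screen and falls down the midline at 25 cm/s. The participant controls a
2 × 0.5 cm paddle inside a 28 × 3.5 cm workspace and must touch the falling
target with any part of the paddle before the target's bottom edge passes the
bottom of the workspace. On *jump* trials the target is displaced
instantaneously 3 or 6 cm to the left or right at one of three heights above
the start area — 11.25, 8.75 or 6.25 cm — leaving about 450, 350 or 250 ms to
respond (low / medium / high *urgency*, the onset height divided by the
target speed). Blocks come in two *certainty* regimes: every trial jumps
(high certainty) or only 60% do (low certainty), the remaining 40%
continuing straight down the midline. At the 37 cm viewing distance 1 cm on
screen subtends 1.5 degrees of visual angle
(`atan(length / viewing_distance)`, the small-segment convention).

The coordinate frame has its origin at the start-area centre, x rightward
and y upward, every position in cm and every time in ms from target motion
onset. Hand position is sampled at 1000 Hz and the right eye at 500 Hz.

The published per-urgency interception counts (32 or 28 per block type) do
not uniquely determine per-block totals; the default allocation in
`default_allocation()` uses 32 jumps per urgency in the constant-size
high-certainty blocks, 28 per urgency and size in the mixed high-certainty
block, 28 jumps per urgency plus 56 no-jump trials in the constant-size
low-certainty blocks and 32 per urgency and size plus 128 no-jump trials in
the mixed low-certainty block. This reproduces 960 trials per session with an
exact 60/40 split in every low-certainty block while using only those two
counts; the allocation is an ordinary tibble and can be replaced wholesale.
Block order groups one certainty regime before the other (configurable) with
jump-size order shuffled by the seed, and trial order is shuffled within
blocks with urgency equiprobable among jump trials and directions balanced
within every (urgency, size) cell — `validate_schedule()` counts all of this
exactly rather than sampling it.

## Measurement conventions

The analysis chain follows the paradigm's standard conventions:

* **Filtering.** Hand position: third-order zero-phase (forward–backward)
  Butterworth low-pass at 20 Hz. Eye position: second-order zero-phase
  Butterworth at 15 Hz. Zero-phase filtering for the eye is a package choice
  (order and cutoff are arguments); it keeps the two streams comparable on a
  common timeline. `signal::filtfilt` applies no edge treatment, so both
  filters pad the trace by odd reflection over about five filter time
  constants and drop the padding afterwards; without this a trace that
  starts away from zero carries a visible startup transient.
* **Differentiation.** Central differences on the native sample grid
  (one-sided at the ends); speed is the Euclidean norm of the planar
  velocity and the "acceleration" used by the saccade criterion is the
  signed rate of change of speed. Streams are analysed at their native rates
  and compared on a millisecond timeline; the eye is never resampled to
  1000 Hz (no fabricated samples).
* **Saccade detection.** A saccade is a maximal run of at least five
  consecutive samples of filtered eye speed above 30 cm/s (on screen, 2-D
  speed, exactly as the criterion is stated). The onset is the last
  acceleration sign reversal at or before the run start and the offset the
  first reversal after speed falls below the criterion. Two
  operationalisations are needed where the verbal rule is silent: the
  reversal search is bounded at 100 ms around the threshold crossing (ties
  toward the earlier sample for onsets, later for offsets), and the sign
  test carries a dead band of 1% of the event's peak acceleration. The dead
  band matters only for near-noiseless data, where the decaying ripple that
  zero-phase filtering leaves behind earlier events (at the 1 cm/s² scale,
  orders of magnitude below saccadic acceleration) would otherwise
  masquerade as a sign reversal tens of milliseconds early. Events closer
  than 10 ms are merged. No minimum-amplitude criterion is applied.
* **Eye latency.** The first detected saccade with onset at least 50 ms
  after the jump (inclusive bound), minus the jump time.
* **Hand latency.** The extrapolation method: on the jump-direction-signed
  horizontal velocity, a line through the last upward crossings of 25% and
  75% of the peak (linearly interpolated between samples) is extrapolated
  back to zero velocity. Trials whose peak signed velocity stays below
  2 cm/s count as "no response". Negative values are returned as such so the
  caller can flag them.
* **Interception.** The paddle is an axis-aligned rectangle centred on the
  hand; contact is the first sample at which the distance from the target
  centre to that rectangle is at most the target radius, and the
  interception succeeds if contact precedes the target's exit from the
  workspace.
* **Flags.** Trials are excluded when an eye-signal gap of at least 40 ms
  intersects the window from motion onset to interception (`signal_loss`) —
  shorter gaps are bridged by linear interpolation for filtering continuity
  but stay masked in the output — or when the hand moved preemptively
  (`preemptive`): provisional latency under 120 ms, or at least 0.5 cm of
  displacement opposite to the jump before any same-sized displacement
  toward it. The 0.5 cm magnitude operationalises "moved to the opposite
  side", which the verbal rule leaves unquantified.

## Movement vigor

For each participant and effector the amplitude–peak-velocity relation is
fitted with the saturating hyperbola

$$v = \alpha \left(1 - \frac{1}{1 + \beta x}\right),$$

pooling all unflagged trials of that participant (vigor is a
within-participant construct; conditions are then compared through the
ratio). Hand amplitude is the farthest excursion from the position at motion
onset up to the interception; hand peak velocity is the peak 2-D speed of
the movement (the component-versus-2-D choice is configurable in principle;
2-D speed is the default because the hyperbola is fitted to movement speed,
not to a single component). Eye points are the detected saccade's
onset-to-offset amplitude and peak speed. Fits use Levenberg–Marquardt
least squares with multi-start initialisation ($\alpha_0 = 1.1 \times$ the
largest observed velocity; $\beta_0 \in \{0.1, 1, 10\}$) because the
saturating form stalls from poor $\beta$ starts, and require at least 20
points (configurable). *Vigor* is the ratio of a movement's observed peak
velocity to the fitted expectation at the same amplitude; values above 1
mark movements faster than that participant's average movement of the same
extent. Vigor is undefined below 0.1 cm amplitude, where the expected
velocity vanishes.

Because vigor is a ratio against a pooled within-participant fit, a
condition's vigor shift is recoverable exactly only when the manipulated
conditions average out across the fit — a balanced manipulation (e.g.
multipliers 0.8 / 1.0 / 1.2 across urgency levels) leaves the pooled curve at
the participant's baseline, and the package's generator defaults keep the
hand multipliers symmetric around 1 for the same reason.

## The synthetic cohort generator

No public dataset exists for this paradigm, so the generator is a
first-class part of the package: it produces cohorts with known ground truth
against which every downstream stage is tested.

**Movement primitive.** Both effectors move along minimum-jerk
displacement profiles (smooth, bell-shaped velocity with peak
$1.875\,A/T$), which match the qualitative shape of recorded interception
corrections and saccades; movement duration is set by the participant's
ground-truth main sequence, $T = 1.875\,A / v_{peak}(A)$.

**Latencies are programmed on the measurement scale.** Both latency
read-outs are operational conventions, and the generator treats the drawn
latencies as values on those scales:

* The extrapolated foot of a minimum-jerk velocity bell lies a fixed
  fraction of the movement duration *after* the physical movement start
  (closed form: the chord through the 25% and 75% points of
  $v \propto \tau^2(1-\tau)^2$ meets zero at $\tau \approx 0.0612$). The
  hand generator therefore launches the movement $0.0612\,T$ early, so the
  extrapolation method reads back exactly the drawn reaction time.
* Zero-phase low-pass filtering spreads the foot of a saccade's velocity
  bell backward by roughly 15 ms (for a 60 ms saccade through the 15 Hz
  filter), so the detected onset leads the physical one. For every reactive
  saccade the generator measures this offset on a template with the
  identical local geometry (the same displacement vector riding on the same
  pursuit drift, through the same filter–differentiate–detect chain) and
  shifts the physical onset so the detected latency equals the drawn one.

Empirical latencies reported with these conventions carry the same offsets,
so programming on the measurement scale is what makes simulated read-outs
comparable to published values. It also gives the pipeline a closed
ground-truth loop: on a noiseless cohort the recovered latencies match the
programmed ones to within one sample (the residual is grid quantisation),
which the acceptance checks exercise at full scale. For the same reason the
recorded interception outcome is computed on the noise-free hand trace
passed through the standard hand filter: contact is a geometric threshold,
and at corner grazes with micron margins the raw and filtered trajectories
can disagree.

**Eye behaviour.** Before the jump the eye drifts down at
`pursuit_gain` × target speed from a jittered fixation point — the default
gain of 0.3 reproduces the characteristic pre-jump eye speed of about
7.5 cm/s, well below the 25 cm/s target — optionally interrupted by one
catch-up saccade that re-foveates half the eye–target gap
(`catchup_prob = 0.55`; pre-jump behaviour in this paradigm is a mixture of
fixation, pursuit episodes and catch-up saccades, so the generator exposes a
mixture weight rather than asserting one regime). A reactive saccade follows
the jump on 93% of jump trials, lands at the jumped target's horizontal
position scaled by an 11% undershoot and at its vertical position at
saccade end plus an urgency-specific landing error (leading the target at
low urgency, trailing it at high urgency), after which the eye tracks the
target velocity. Blinks (6.5% of trials, 120 ms) are masked samples, never
interpolated values, so preprocessing must handle them explicitly.

**Hand behaviour.** The paddle holds near the start-area centre; on jump
trials a lateral correction of amplitude `jump_size − undershoot_cm`
(default undershoot 1 cm, placing 3-cm jumps about 2 cm from the midline —
contact with the outer paddle edge; a single constant cannot simultaneously
reproduce the larger undershoot seen for 6-cm jumps, a known simplification)
is launched at the drawn latency with peak velocity equal to the
urgency-specific vigor multiplier times the main-sequence value. Preemptive
trials (8.5%) either start 40–110 ms after the jump or move to the wrong
side. Non-preemptive latency draws are truncated at 125 ms and preemptive
draws kept at or below 110 ms, so the 120 ms flagging boundary cannot flip
on sub-millisecond measurement differences — this is what lets flag counts
be compared to the generator's bookkeeping *exactly* rather than
approximately.

**Default parameters.** Cell means are built from the paradigm's reported
group values: hand latencies averaging 188.8 ms, decreasing monotonically
with urgency (19 and 24 ms faster at medium and high urgency than at low);
eye latencies averaging 135.4 ms and fastest at *medium* urgency (5 and
11 ms slower at low and high); both effectors 14 ms faster under high than
low certainty; a within-cell eye–hand latency correlation of 0.3. These are
generator defaults that make simulated cohorts resemble published ones —
they are never used as test oracles, since the underlying human data are not
public. Between-participant variability draws main-sequence parameters
uniformly from plausible ranges (hand α 75–105 cm/s, β 0.18–0.32 /cm; eye
α 300–400 cm/s, β 0.15–0.25 /cm), pursuit gain from 0.2–0.4 and shifts each
participant's latency tables by Gaussian offsets (12 ms hand, 8 ms eye).

## Condition-level statistics

Per-trial measures are collapsed to medians per participant and
(certainty, urgency) cell, over unflagged jump trials, restricted to
saccade-present trials for the eye measures and collapsed over jump size by
default. The 2 × 3 repeated-measures ANOVA uses the classical univariate
partitioning with participant error strata and uncorrected degrees of
freedom (urgency terms carry $(2, 2(n-1))$; a sphericity correction is not
applied by default because the paradigm's reported statistics are
uncorrected). Effect sizes are reported as partial eta squared — reported
magnitudes of the order of 0.6–0.9 alongside $F(2,24)$ statistics are
consistent with the partial, not generalised, form. A term with zero effect
sum of squares is reported as $F = 0, p = 1$ rather than 0/0. Post hoc
comparisons are two-sided paired t-tests with Bonferroni correction within
two families (the certainty pair; the three urgency pairs), with Cohen's d
as mean difference over the SD of differences.

The trial-by-trial coupling model is a linear mixed model,

```
hand ~ 1 + eye * certainty * urgency + (1 + eye | participant)
```

with predictors standardized before fitting. Urgency enters as a centred
numeric covariate (a single reported coefficient per term implies
non-categorical coding) and certainty as a standardized low-certainty
indicator; both choices are documented rather than hidden in defaults.
Singular random-slope fits fall back to a random intercept with a warning.
Confidence intervals are Wald 95% and p-values use Satterthwaite degrees of
freedom. Per-participant Pearson correlations between eye and hand latency
per urgency level complement the model.

## Problem sizes and numerical choices

The package's own validation runs use: the full 13-participant noiseless
cohort (12,480 trials) for ground-truth closure (eye latency within one eye
sample and hand latency within 5 ms on at least 99% of unflagged jump
trials; interception outcomes matching exactly); 1000 random synthetic eye
traces for the equivalence of the vectorised saccade detector with a
literal loop-based run-length scan; 200 simulated participants for
main-sequence recovery (median α error under 5% at 10% velocity noise;
balanced 0.8/1.0/1.2 vigor cells recovered at 1.2 ± 0.02); 500 null cohorts
for ANOVA type-I calibration at α = 0.05; and 25 replicates of 13 × 576
jump trials for the mixed model's power to detect a programmed r = 0.3
eye–hand coupling.

Numerical details worth knowing: filters use reflection padding (above);
nearest-sample lookups are used for epoch positions (masked samples give
`NA`); the 50 ms first-saccade bound is inclusive; merged saccade events
share one onset/offset pair; degenerate inputs (constant traces, empty
cells, all-flagged cells, zero-variance difference vectors) return exact
zeros, `NA`s or errors as documented per function rather than propagating
`NaN`s.

## What passing tests do and do not show

The generator produces smooth, single-correction movements with known
latencies, stationary noise and simple artifact models. Passing recovery
tests therefore demonstrates that the analysis chain is internally
consistent and implements the stated conventions exactly — not that it is
robust to everything real data contain (pupil-size artifacts around blinks,
lens wobble at saccade ends, drift in tracker calibration, multi-component
hand corrections, online corrections after the first response). Eye peak
velocities measured after 15 Hz filtering are attenuated relative to the
physical saccade, more so for shorter saccades; this affects real analyses
equally and cancels in vigor ratios only to the extent that amplitudes are
comparable across the cells being contrasted. The neural interpretation of
the paradigm and any real-time considerations (display latency handling,
force feedback) are out of scope; the ~50 ms display latency is modelled
only as a constant visuomotor delay inside the generator.
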