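---
title: "Methods: single-unit analysis of the constructive memory-perception task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-unit analysis of the constructive memory-perception task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The task and its geometry

The constructive memory-perception (CMP) task separates memory retrieval
from its use.  Each trial presents an item cue (0-300 ms), a delay, a
large background image at a randomized orientation (1000-1300 ms), a
second delay, and a 4-alternative saccade choice (from 2000 ms).  Eight
visual items, two "sets" A and B, are pairwise assigned to four
co-locations (I-IV) on the background; the two items of a pair are
visually unrelated but share a location, so equivalent ("unitized")
responses to them indicate retrieval of the common location.  The target
is the cued item's co-location carried along with the rotated background:

    target = (default_angle[colocation] - theta) mod 360

with the default angles on the four diagonals (canonical layout I = 45,
II = 315, III = 225, IV = 135 degrees) and positive orientation theta
displacing locations clockwise on screen.  This sign convention is the
unique one consistent with the worked cue-combination examples of the
task (e.g. co-location II on a -90 degree background is top-right, and
[I, +90] / [III, -90] both map to bottom-right).  The layout is
configurable because different animals can learn different
item-location association patterns.  Sessions test the five orientations
-90, -45, 0, 45, 90 degrees; the 8 x 5 = 40 configurations are scheduled
by shuffled balanced blocks, so counts never differ by more than one
(the recorded sessions only state "pseudorandom"; the block design is
the package's choice, making small sessions exactly balanced).

## The synthetic-session generator

Every downstream statistic is validated against sessions with a known
truth.  Each simulated neuron is an inhomogeneous Poisson emitter whose
rate is a piecewise-constant function of the trial, drawn from one of
eight archetypes that mirror the response classes seen in the
hippocampus during this task: `untuned`, `item_unitized` /
`item_nonunitized` (item-cue-period responses with or without the
co-location memory effect), `background` (orientation-tuned responses
after background onset), `convergent` (a co-location signal persisting
into the early background period plus an orientation gain 200-500 ms
after background onset, overlapping on the same cell), `transferring`
(fires only when the retrieved location has been rotated onto the
neuron's preferred screen position, i.e. target preferred *and* theta
different from 0), `targeting` (fires for its preferred target
regardless of the cues, late in the background period, plus an
item-period component whenever the cued co-location's 0-degree position
is the preferred target -- the "default orientation" effect), and
`multiphase` (convergence, then transference, then targeting in
succession).

Defaults, chosen once as the study conditions and not revisited: 128
trials per session, baseline 5 Hz (all cells satisfy the 1 Hz inclusion
floor applied to recorded data), gain twice the baseline, error rate
0.15 (between the two recorded animals' error rates of roughly 19% and
3%), with erroneous choices uniform over the three distracter
positions.  The default 456-neuron mix mirrors the size of the recorded
data set; reduced presets keep test runs fast without touching effect
sizes.  Co-location tuning is graded (multipliers 1, 0.4, 0.15, 0.05 by
cyclic distance from the preferred co-location) rather than
all-or-none, because recorded item-selective cells respond in a graded
fashion across items; the `unitization` parameter in [0, 1] scales the
set-B item's share of each co-location's gain, so unitization 1 makes
the expected set-A and set-B rate vectors identical and unitization 0
decorrelates them.  For target-coding archetypes a `choice_weight`
(kappa) mixes the instructed and the chosen target: kappa = 1 makes
error-trial activity follow the upcoming choice, kappa = 0 the
instruction; correct trials are unaffected.  The recorded phenomenon
is descriptive, not generative, so this mixture is the package's
modeling choice to give the error analysis a recoverable truth.

Spikes are sampled by thinning against the profile's maximum rate
(exact for bounded rates) and quantized to integer microseconds so CSV
round trips are bit-exact.  A single session seed expands into fixed
per-neuron substreams; adding neurons to a specification never perturbs
the spike trains of existing ones.

What the generator does *not* emulate: non-Poisson spiking statistics
(bursting, refractoriness), rate drift and adaptation within or across
trials, eye-position covariates, correlated noise across neurons, and
learning.  Passing tests therefore certify the analysis code and its
calibration under Poisson variability at realistic rates and counts --
not robustness of the scientific conclusions to those biological
complications.

## Rate representations

Firing rates are spike counts over half-open `[start, end)` windows
divided by window length; half-openness (unstated in the original
methods) prevents double counting at shared edges.  The screens use 8
consecutive 300-ms windows stepping by 100 ms over 0-1000 ms from cue
onset; single-window summaries use 60-1000 ms (treated half-open at
both ends); time courses use 100-ms windows stepping by 1 ms (tests and
the reduced profile step 5-20 ms purely to bound runtime -- the
estimator is identical).  Spike-density functions are sums of unit-area
Gaussian bumps (sigma 20 ms) on a 1-ms grid, truncated at 5 sigma,
where the truncation and grid errors are far below statistical
resolution (the single-spike integral is conserved to 0.1%).

## Classification screens

Item selectivity during the item-cue period: one-way ANOVA across the 8
item cues per window, family level 0.01 with Bonferroni correction over
the 8 windows (per-window 0.00125).  A supplementary description of the
index procedure prints a per-bin threshold of 0.0125, which is not
Bonferroni-consistent with the stated family level; the package
defaults to the Bonferroni-consistent 0.00125 and exposes the threshold
as an argument rather than guessing which was intended.

Background-cue-period selectivity: a three-way nested ANOVA on correct
trials with -90, 0, 90 degree backgrounds only (the 45-degree
orientations would bias target frequencies), with main effects of
co-location (3 df), background orientation (2 df), target (3 df) and
the 8 item cues nested under co-locations (4 df, coded as a set-A vs
set-B contrast within each co-location).  Because the target is
determined by (co-location, orientation), the design is a constrained
Latin rectangle; the package checks estimability and names the missing
factor on failure.  All factors use sum-to-zero coding, and each
factor's F is a model comparison against the full model's residual mean
square (a Type-III-like treatment; the original methods are silent, and
pseudorandom schedules are only approximately balanced, so sequential
sums of squares would depend on factor order).  F statistics are
computed from QR-projection residual sums of squares, which makes the
dense 1-ms sliding screens feasible; linear-model fits serve as
independent test oracles.  One consequence of the Latin constraint,
visible in the recorded example cells too, is that a target-by-
orientation interaction (the transference signature) projects onto the
other main effects, so transferring cells raise all three F curves.
Neurons averaging below 1 Hz over the trial are excluded before any
screen.

## Co-location index and its permutation null

Per significant window, the index correlates the four set-A item means
with the four set-B means ordered by co-location (4 pairs, 2 df);
per-window r values are Fisher-Z transformed, averaged over the
significant windows, and back-transformed (so a single-window index
equals that window's r, and windows with zero variance are skipped with
a warning; with no significant window the index is undefined and the
neuron is flagged).  The permutation null shuffles item labels across
trials (item counts preserved) and recomputes the index with the same
window mask; p is two-tailed with the add-one correction, so it is
never zero.  The alternative of permuting the 8 labels *over items*
(keeping each item's trials together) was considered and rejected: for
a unitized neuron any permutation that lands the two driving items in
the same co-location pair -- at least 1 in 7 -- reproduces a near-1
index, flooring p around a few percent, which is incompatible with the
printed significance of the worked example (p below 1e-4).  The
trial-level shuffle is also the scheme under which the test is exactly
calibrated.

## ROC discriminability

The AUC between two trial groups is the normalized Mann-Whitney
statistic with ties counted one half (equivalent to integrating
cumulative trial proportions over a sweeping rate criterion).  The
null re-partitions the pooled trials 10,000 times (1,000 in the reduced
profile) and relabels the higher-mean partition "optimal" before each
AUC, exactly as the optimal item is determined from data; this
re-determination pushes the null median above 0.5 at finite trial
counts, so the observed AUC must be compared with the permutation
median, not with 0.5.  Note that the optimal item is chosen as the best
of 8 items while the null only re-determines the better of two groups;
the test is therefore liberal for the optimal-vs-pair comparison, which
is the direction that strengthens the finding it is used for (most
high-index cells fail to discriminate an item from its partner even
under a liberal test).

## Construction analyses

*Orientation-tuning similarity*: for each co-location-selective neuron,
the correlation (3 pairs, 1 df) between the responses to the three
orientations for the best and the second-best co-location (fixed from
the 60-1000 ms means), computed whole-window and in sliding bins; the
population time course is tested per step with a two-tailed signed-rank
test at 0.01.  A positive epoch shortly after background onset is the
convergence signature.

*Matching index*: per neuron, the item-period co-location means are
re-sorted to the screen positions they would occupy under each
hypothesized background orientation (-90, 0, +90) and correlated with
the background-period target means (4 pairs, 2 df).  A population
median that is maximal and positive only for the 0-degree pattern
indicates the retrieved location is represented at its
default-orientation screen position.

*Target population SDFs*: per target-selective neuron, per-target SDFs
aligned to background onset are computed separately for 0-degree and
rotated (+/-90) trials, normalized by the amplitude of the mean
response to the best target (the 60-1000 ms mean, "amplitude of the
mean" rather than the peak -- the methods text is ambiguous; the choice
is exposed), and the best target's curve has the mean of the other
targets subtracted.  Normalization is per neuron before pooling.
Per-step two-tailed t tests at 0.05 compare each group with zero and
the rotated group with the 0-degree group; a rotated-above-0 epoch in
the mid background period is the transference signature, its
disappearance late in the trial the targeting signature.

*Error analysis*: for each target-selective neuron with at least 10
error trials, three arrays per 300-ms background-period bin: D, the
error-trial rates; X, the mean correct-trial rate for the position the
animal wrongly chose; Y, the same for the missed correct position
(templates over all correct trials, hence up to 8 screen positions).
In qualifying bins -- nested-ANOVA target effect significant on correct
trials at the Bonferroni per-bin level and mean rate above 1 Hz -- the
first-order partial correlations pcor(D, X | Y) and pcor(D, Y | X) are
computed by the standard formula (equivalent to correlating
regression residuals, which is the test oracle), Fisher-Z averaged over
qualifying bins, and compared across the population with a two-tailed
signed-rank test.  The per-neuron test's n - 3 degrees of freedom match
the worked example (47 df at 50 error trials).

## Numerical and calibration choices

Permutation p values use the add-one correction on numerator and
denominator.  Degenerate inputs are handled explicitly: zero-variance
windows give F = NA and count as not selective; zero-variance 4-vectors
skip a window (index) or flag a pattern undefined (matching index);
neurons without a usable window are excluded with a logged reason, and
loading a session re-validates every geometric invariant, failing with
the offending row rather than dropping it.

Calibration is verified on 500 simulated untuned neurons.  The
family-wise rate of the ANOVA screens is checked as a one-sided bound
(observed rate must not exceed 0.01 beyond binomial error): Bonferroni
over eight *overlapping* windows is conservative by construction, so
the family rate sits below the nominal level and an equality check
would be wrong.  The co-location permutation null is exactly uniform
and is checked two-sided at the 0.05 rejection level; the AUC
permutation p is slightly super-uniform (add-one correction) and is
checked as a one-sided bound on pre-specified exchangeable groups.

Problem sizes used by the test-suite and acceptance runs -- 500-neuron
calibration sessions, 8-60 neurons per recovery ensemble, 1,000
permutations, 5-20 ms time-course steps -- were chosen as the smallest
scales at which every property is stable, with the full
456-neuron / 10,000-permutation profile available via
`default_config("full")`.

## Known limitations

The generator's simplifications listed above bound what green tests
mean.  The nested ANOVA treats neurons as fixed-effect units and does
not model interactions explicitly (the constrained design aliases some
interactions onto main effects, as in the original analysis).  Single-
neuron tuning-similarity and matching correlations use 3-4 support
points and are individually very noisy; only their population
statistics are interpreted.  The worked-example check of the
co-location index requires the published per-neuron source-data table,
which is not redistributed with the package; the test states the
expectation and fails cleanly when the table is absent.
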