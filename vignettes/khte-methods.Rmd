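---
title: "Methods: quantifying psychomotor state change from key hold times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying psychomotor state change from key hold times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The signal and its assumptions

Pressing and releasing a key is a stereotyped motor act whose duration — the
key **hold time** (HT), press to release of the same key, typically around
100 ms — engages sensorimotor circuitry that psychomotor impairment is known
to affect. `khte` treats the hold times of one typing session as an
irregularly sampled stochastic process *a*[*t*] indexed by press time, and
asks two questions: *where* the hold-time distribution sits, and *how
stable* it is over the course of a session. The method is deliberately
content-agnostic: nothing about which keys are struck, the language, or the
text enters the analysis, only event timing. The working assumptions are:

- hold times are positive, short (~0.1 s), and their distribution changes
  slowly relative to a window of tens of seconds;
- impairment expresses itself as some combination of a *shift* of the
  distribution's bulk toward longer holds and an increase in its
  *temporal instability*;
- subjects serve as their own controls: all inference is about *changes*
  between two sessions of the same subject, never absolute levels, which
  removes the (large) between-subject differences in typing style.

## From events to the KHTE matrix

`extract_hold_times()` matches each key-down to the earliest subsequent
key-up of the same key, so rollover typing — holds of different keys
overlapping — is handled naturally. Three event pathologies are resolved by
explicit rules rather than silently: a second down of an already-held key is
OS auto-repeat and is discarded (the original press time is kept, since
auto-repeat is not a finger action); ups without an open down and downs
never released are orphans, dropped and counted in a diagnostics record; a
zero-length hold is a timer artifact (acquisition timers resolve a few ms)
and is dropped. Every event is accounted for by exactly one counter, a
bookkeeping identity the test suite asserts.

`khte()` then builds the **Key Hold Time Evolution matrix**. The session
`[0, duration]` is partitioned into consecutive, non-overlapping windows of
`N` ms aligned to t = 0; a sample at press time *t* belongs to window
`floor(t/N)`. Natural typing pauses, so sparse windows carry almost no
distributional information: windows with fewer than `Q` samples are removed,
and retained windows keep their original index so the time axis stays
honest. Each retained window becomes a histogram over `k` equal bins from 0
to `M` ms whose last bin also absorbs every observation above `M`, divided
by the window's sample count. Columns are therefore exact discrete
probability vectors (they sum to 1), and the matrix is a time-evolving
density estimate. A histogram rather than a kernel/parametric density is a
considered choice: at natural speeds a window holds only one or two hundred
samples, no distributional form is safe to assume, and the histogram mode is
robust at those counts.

Numerical conventions, chosen for determinism: bin membership uses
half-open intervals `[edge, next_edge)` — a value exactly on an internal
edge goes to the upper bin, consistent with the overflow rule; windows do
not overlap (overlapping windows would correlate adjacent columns and
complicate the self-similarity interpretation).

## The two features

**KHTE peak** (*K*ᵖ): for each column take the argmax bin — ties broken
toward the lowest bin index, a deterministic rule — and represent it by its
bin center; the overflow bin, which is unbounded, is represented by
`M + M/(2k)`, half a bin-width past its lower edge. *K*ᵖ is the mean of
these representatives over windows, in milliseconds.

**KHTE self similarity** (*K*ˢ): compute the z × z matrix of Euclidean
distances between columns, normalize by a saturation scale `L` with clipping
(`min(d/L, 1)`), and set *K*ˢ = 1 − mean off-diagonal entry. Viewing windows
as nodes of a fully connected graph with edge weights `1 − d/L`, this is the
simplest global-connectivity measure; other graph summaries could be
plugged in at `khte_selfsim()`'s input (it accepts any normalized distance
matrix object). Normalizing by a *fixed* scale rather than per-matrix
min–max is essential: it keeps *K*ˢ comparable across sessions, which is
what makes the difference *K*ˢ′ − *K*ˢ meaningful.

## Parameters, units, defaults

| parameter | meaning | default | rationale |
|---|---|---|---|
| `N` (ms) | window length | 60000 | ≥ `Q` keystrokes per window even at ~126 keys/min, the slow end of natural typing |
| `Q` (count) | minimum window occupancy | 30 | enough samples for a usable 20-bin histogram |
| `k` (count) | histogram bins | 20 | with `M` = 500, 25 ms bins resolve the ~100 ms mode |
| `M` (ms) | last regular bin edge | 500 | covers all but pathological holds; rest overflow |
| `L` (distance) | similarity saturation | 0.5 | two 20-bin histograms with 100–250 samples differ by ~0.1 from multinomial noise alone and up to ~0.4 under strong drift, so 0.5 uses the full [0, 1] range without constant saturation |
| `C` | SVM cost | 1 | standard default; the feature space is 2-D and standardized per fold |

`tune_khte_params()` optimizes these by maximizing the mean norm of the
state-change vector over training pairs — an objective that knows the
magnitude of a change but not its direction, so it cannot bake the expected
direction into the parameters. Because `N`, `Q`, `k` are integers, the
search is a coordinate descent over a user-supplied discrete grid (swept to
a fixed point) rather than a literal gradient descent. Training pairs must
be disjoint from evaluation data; the function does not enforce this — the
caller owns the split.

## Change vectors, direction, and the angle convention

For one subject, a reference session (rested) and a second session give
**v**Δ = v′ − v with components `d_peak` (ms) and `d_selfsim`
(dimensionless). Impairment is expected to raise the peak and lower the
self similarity, so the analysis flips the second axis
(`selfsim_orientation = -1`, recorded in dataset metadata) to put the
expected impairment direction in the upper-right quadrant.

The two axes carry incommensurable units, and their typical magnitudes
differ by two orders (tens of ms vs tenths of a unit). A raw two-argument
arctangent therefore collapses every angle onto the peak axis and the
directional analysis would be blind to the stability channel. The package
computes angles on commensurable axes: `d_peak` is divided by the histogram
bin width `M/k` — the resolution of the peak feature, so one bin of peak
change weighs as much as one unit of similarity change — while magnitudes
(used by the tuning objective) stay in raw units. `delta_vector()` defaults
to the raw polar form (`angle_peak_scale = 1`); the pipeline passes the bin
width explicitly, and the scale used is recorded alongside the orientation.

Directionality across subjects is tested with the Rayleigh test: mean
resultant length R̄, statistic z = nR̄², and the classical series
approximation for the p-value, clipped into (0, 1]. The test suite
validates this approximation two ways: its empirical size at α = 0.05 with
n = 14 over 10,000 uniform-null simulations, and approximate uniformity of
the null p-values. The truncated series is accurate down to p ≈ 10⁻⁶; below
that it wiggles at a level far beneath any decision threshold, which is why
the monotonicity property is asserted over the valid range.

## Classification protocol

Positive samples are rested→impaired changes within a repetition (one per
subject per repetition); negatives are the same-state changes across the
two repetitions (rested↔rested and impaired↔impaired, two per subject),
shared between the two evaluation datasets. We read "same negative samples"
as pooling both same-state transition types.

"Hold-one-out" is implemented as leave-one-**subject**-out: a subject
contributes three correlated samples, and holding out single samples would
leak subject identity into the training fold. Sample-level hold-out remains
available behind `loo_unit = "sample"` for comparison. Features are
z-scored with training-fold statistics only; the SVM is linear with libSVM
probability (Platt) outputs. Platt calibration uses an internal random
cross-validation, so `loo_svm_evaluate()` fixes a local seed (argument
`seed`) to make evaluations reproducible without touching the caller's RNG.
Pooled held-out probabilities define the ROC; AUC is the trapezoid over
operating points with tied scores grouped (equivalently, the rank statistic
with half-credit ties — the suite asserts the equivalence and cross-checks
against an independent ROC implementation).

The decision-stump baselines sweep a single threshold through the change in
median hold time (or typing speed) over the *whole* dataset, both
orientations, no train/test split — deliberately an upper bound for what
the raw variable can do, which the cross-validated KHTE classifier is asked
to beat.

One calibration subtlety the suite documents: under a label-permutation
null, *unrestricted* permutation combined with pooled leave-one-subject-out
scores is biased away from AUC 0.5 (labels of different folds become
negatively dependent, and the learner reflects the realized chance
association back at the held-out fold). The valid null for this blocked
design permutes labels within each subject's exchangeability block, which
is what the calibration test does.

## The synthetic cohort generator

No raw typing-session data of this kind are publicly deposited, so the
generator defines the study conditions under which the pipeline is
validated: 14 subjects, two states (rested / impaired), two repetitions at
least a week apart in spirit, 15-minute sessions. Per subject, a
`typist_profile()` is drawn from population ranges bracketing natural
typing: speeds 126–281 keys/min, median holds near 100 ms, occasional
multi-second pauses.

A session is generated as a gamma renewal process of inter-press gaps
(calibrated so realized speed matches the target after accounting for
exponential pauses), with log-normal hold times around a location that
follows a bounded, mean-reverting random walk updated once per minute — the
within-session instability channel. Log-normal is a choice, not a claim:
hold times are positive and right-skewed like most reaction-time-like
variables; nothing downstream assumes the form. Two per-session
multiplicative jitters model test–retest (day-to-day) variability of a
subject's median hold time (log-sd 0.08) and speed (log-sd 0.04) — without
them a subject's sessions would be unrealistically reproducible and a
trivial median-threshold would classify perfectly.

Impairment applies three factors: `ht_shift` = 1.22 on the hold-time
location, `instability_gain` = 2.5 on the within-session drift, and
`speed_factor` = 0.93 on typing speed. These effect sizes are the
generator's definition of "impairment like the sleep-inertia literature
describes": they were calibrated, once, so that the *baseline* raw-variable
stumps land in the regime reported for real sleep-inertia typing data
(median-HT stump AUC in the mid-0.7s, speed stump similar) — i.e. the
synthetic task is deliberately not made easy for the raw variables — while
the two KHTE channels (shift and instability) remain individually
informative. Everything the suite then demonstrates (directional
concentration of impaired changes, KHTE beating the stumps, null effects
undetectable) is a property of the pipeline at those fixed conditions, not
of per-test tuning.

What the generator does **not** emulate: linguistic key sequences and
key-identity structure (irrelevant to a content-agnostic method), fatigue
trends within a session, learning effects across repetitions, heavy-tailed
pause bursts from task switching, and device/timer quantization beyond
0.1 ms rounding. Passing tests therefore show the pipeline recovers the
kinds of effects the generator encodes at realistic magnitudes — they are
not evidence about any specific real cohort.

## Problem sizes and runtime choices

The validation suite runs, per default configuration: exact-oracle
equivalence on 1000 random small instances per operation; 10,000
uniform-null Rayleigh simulations at n = 14; 200 blocked label
permutations of the SVM evaluation; 50 replicate 14-subject cohorts at the
full 15-minute session length plus 8 null-effect cohorts. These sizes keep
the whole suite around a minute on one CPU while holding Monte-Carlo error
well inside the asserted tolerances.

## Known limitations

- The global-connectivity summary is one of several reasonable reductions
  of the self-similarity matrix; results for alternatives (efficiency,
  clustering coefficients) may differ.
- The Rayleigh p-value is a series approximation; agreement with other
  software is expected to the ~10⁻⁶ level, not beyond.
- With 14 subjects, AUC estimates carry sampling noise of several
  hundredths; single-cohort numbers should be read accordingly.
- The angle commensuration ties the directional analysis to the histogram
  resolution `M/k`; changing the binning changes the angle geometry (though
  not the quadrant structure).
- Flight time, press/release latency and other keystroke-dynamics variables
  are out of scope by design; the method is a hold-time method.
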