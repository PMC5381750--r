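# khte — Key Hold Time Evolution analysis of natural typing

`khte` detects changes in psychomotor state from the *timing* of natural,
uncontrolled typing — no control over what is typed, which keyboard is used,
or how fast the typist goes. The motivating application is the detection of
transient psychomotor impairment (e.g. sleep inertia, the groggy state right
after waking) from the key hold times of everyday keyboard use, a signal that
is content- and language-agnostic and cheap to collect at scale.

## The method

The unit of analysis is the **hold time** (HT): the interval between the
press and the release of one key, typically ~100 ms in natural typing, and
sensitive to psychomotor slowing.

1. **Hold-time series.** A raw log of key-down/key-up events is reduced to
   the process *a*[*t*] of (press time, hold time) pairs, with per-key
   matching so rollover typing is handled, and orphan/auto-repeat events
   dropped and counted.
2. **KHTE matrix.** The session is cut into consecutive windows of *N* ms;
   windows with fewer than *Q* keystrokes are discarded; each retained
   window becomes a normalized histogram over *k* equal bins on [0, *M*] ms
   (the last bin absorbs everything above *M*). The columns form the
   k × z matrix **K** — a time-evolving estimate of the hold-time density.
3. **Compact features.**
   - *K*ᵖ (**KHTE peak**): the mean, over windows, of each histogram's mode
     location — rises with psychomotor slowing;
   - *K*ˢ (**KHTE self similarity**): 1 minus the mean off-diagonal entry of
     the window-to-window L2 distance matrix (normalized by a saturation
     scale *L*) — falls as the hold-time distribution becomes temporally
     unstable.
4. **State-change vectors.** Two sessions of a subject give
   **v**Δ = (*K*ᵖ′, *K*ˢ′) − (*K*ᵖ, *K*ˢ). Its direction encodes the kind of
   change: impairment is expected to raise the peak and lower the self
   similarity. Directionality across subjects is tested with the **Rayleigh
   test** for circular uniformity.
5. **Classification.** Positive samples are rested→impaired changes within a
   repetition; negatives are same-state changes across two repetitions. A
   linear SVM (libSVM, with probability outputs) is evaluated
   **leave-one-subject-out**; decision-stump baselines on median hold time
   and typing speed provide the raw-variable upper bounds.

Because raw typing data of this kind are not publicly deposited, the package
ships a calibrated synthetic keystroke generator (`generate_session()`,
`generate_cohort()`) that emulates 15-minute sessions at natural typing
speeds, with impairment modeled as a hold-time shift plus increased temporal
instability, so the entire pipeline is exercisable and testable end to end.

## Worked example

```r
library(khte)

# one synthetic 15-minute typing session, fitted to a KHTE matrix
log <- generate_session(typist_profile(seed = 42), duration_ms = 900000)
fit <- khte(log)
summary(fit)
#> KHTE fit: 20 x 15 matrix (191--233 samples/window)
#>   KHTE peak (K^p):           89.17 ms
#>   KHTE self similarity (K^s): 0.799

# a full 14-subject study: 2 states x 2 repetitions per subject
cohort <- generate_cohort(n_subjects = 14, master_seed = 1)
study <- khte_study(cohort)
study
#> Key hold time evolution study
#>   56 sessions, 14 subjects in the change datasets
#>   repetition1: KHTE SVM AUC 0.962 | stump AUC: median HT 0.918, speed 0.804 | Rayleigh p 8.5e-07
#>   repetition2: KHTE SVM AUC 0.954 | stump AUC: median HT 0.712, speed 0.819 | Rayleigh p 0.00049
#>   same-state changes: Rayleigh p 0.75
```

Reading the output: the rested→impaired change vectors point in a common
direction (Rayleigh p ≪ 0.001 in both repetitions) while same-state changes
do not (p = 0.75); the KHTE features separate impaired from same-state
changes under leave-one-subject-out evaluation (AUC ≈ 0.95) better than a
decision stump on either raw variable. `plot(study)` draws the ROC curves,
`plot(study, "deltas")` the change vectors, and `plot(khte(log))` the matrix
itself as a time–hold-time heatmap.

A thin command-line front end with subcommands
`simulate | featurize | test-direction | classify | replicate` lives at
`inst/cli/khte.R` (`system.file("cli", "khte.R", package = "khte")`).

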