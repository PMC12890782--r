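---
title: "Residual dynamics of task-evoked EEG: model, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual dynamics of task-evoked EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question and the model

Trial-averaged ERPs describe what the brain does *on average*; what happens
to the deviations around that average is equally informative. If cortical
circuits behave like a dynamical system with attractor-like stability,
a perturbation away from the mean trajectory should decay back toward it,
and the *rate* of that decay is a property of the underlying recurrent
circuitry. This package quantifies that rate from multichannel EEG recorded
during a Flanker task, in a longitudinal three-group design (never-
institutionalized, foster-care, and care-as-usual groups assessed at 12, 16
and 21 years).

The chain is:

1. **Preprocessing.** 50 Hz notch (2nd-order IIR, Q = 30), 1 Hz high-pass
   (4th-order Butterworth), 20 Hz low-pass (2nd-order Butterworth),
   downsampling to 40 Hz, epoching to half-open [-1, 1) s windows around
   the flanker stimulus and around the response (80 samples each), and a
   per-channel z-transform within each participant-visit over all pooled
   epoched samples.
2. **State space.** Condition-averaged ERPs for the four cells
   (congruent/incongruent x correct/error), each alignment, are
   time-concatenated into an N-channel x (2 x 4 x 80) grand matrix,
   averaged over all participant-visits with equal weight. PCA of its
   channel covariance yields a single 2D basis shared by everyone — so
   group or age differences downstream cannot come from basis differences.
3. **Residuals.** Every trial is projected into the 2D space and its
   condition-cell mean trajectory subtracted:
   `x[i,j,t] = s[i,j,t] - sbar[j,t]`.
4. **Dynamics.** In a 200 ms moving window (8 samples at 40 Hz, sliding by
   one sample = 25 ms), all trials' consecutive-sample pairs are pooled and
   the first-order autoregression `x[t+1] = A x[t] + e[t]` solved by least
   squares without an intercept (residuals are mean-zero by construction).
   The *moduli* of the eigenvalues of each window's `A`, sorted descending,
   are the statistic of interest: values near 1 mean perturbations persist;
   values near 0 mean fast relaxation to the mean trajectory.
5. **Statistics.** Timewise mixed models (Group x Age on each eigenvalue,
   random intercept per participant), Benjamini-Hochberg FDR over time
   within each effect x alignment family, contiguous significant clusters,
   cluster-averaged eigenvalues for Bonferroni post hocs, an
   eigenvalue-BIS coupling model, and bootstrap mediation
   (age → eigenvalue → BIS; institutionalization → eigenvalue → BIS) with
   bias-corrected and accelerated intervals.

## Why moduli, and how "first/second" is defined

A 2x2 dynamics matrix can have complex-conjugate eigenvalues (spiralling
dynamics). Their moduli are equal and real, which keeps the eigenvalue
trajectories real-valued and comparable across windows; we therefore
analyse moduli, sorted descending within each window, rather than real
parts or a component-identity pairing. With the generator's default
diagonal dynamics the sorted moduli coincide with the two latent decay
rates, which is what makes ground-truth recovery testable.

## The synthetic cohort: what it emulates and what it does not

No real recordings ship with the package; a generator produces a cohort
with the statistical structure the analysis assumes, plus the ground truth
needed to audit it.

* **Design**: 60/52/51 participants in the three groups, all assessed at
  12, 16 and 21 y; 56 channels; 20 practice + 160 test trials per session.
* **Latent dynamics**: each visit has true eigenvalue trajectories
  `clip(base + slope*(age-12) + group_offset + subject_offset, 0, 0.98)`.
  Defaults: constant base (0.75, 0.55), slope -0.010/y, group offsets
  NIG 0, FCG +0.05, CAUG +0.06, subject SD 0.04. The base is constant over
  trial time by default because the response-aligned ground truth is then
  well defined (a time-varying base indexed to flanker time would be
  smeared across trials by variable RT); time-varying profiles are
  exercised in the tests, not as cohort defaults.
* **Trials**: 2D AR(1) residuals (innovation covariance 1.5·I) plus
  condition-mean templates (sums of Gaussian bumps: stimulus-locked bumps
  on component 1, larger for incongruent; a response-locked bump on
  component 2, much larger on errors — an error-monitoring analogue),
  mixed into channels through a random orthonormal 56 x 2 forward model
  with white sensor noise (SD 0.2, chosen so the two latent components
  dominate the grand-ERP covariance).
* **Behaviour**: a logistic observer of presentation time per condition.
  The congruent asymptote is high and fixed; the incongruent asymptote
  rises with age and is lower in the ever-institutionalized groups.
  Because the adaptive staircase (+-50 ms on cumulative accuracy, strict
  ">" at the 60% target, start 400 ms, bounds [50, 1000] ms) equalises
  *overall* accuracy, the group/age structure survives mainly in
  condition-specific accuracy — which mirrors how such staircases behave
  with real participants. RTs are log-normal with age, condition, group
  and subject effects. A `mediation_gain` term adds the participant's true
  mean eigenvalue to log-RT, making the eigenvalues a *genuine* mediator
  of age and group effects on performance, so the mediation stage has a
  true positive to find.
* **Observer calibration**: the defaults were fixed once, before any
  acceptance run, so that overall accuracy lands within the staircase band
  (~61.5%), each condition x correctness cell has well over 10 trials in
  expectation, and the qualitative orderings (incongruent accuracy rising
  with age, NIG above the ever-institutionalized groups early, groups
  converging by 21) hold.

What the generator does **not** emulate: scalp biophysics (no forward head
model), ocular/muscle artifacts (the blink-removal stage is an identity
hook), pink-noise background, or volume-conduction channel correlations.
Passing tests therefore certify the *analysis machinery* — recovery of
known dynamics, calibrated inference — not robustness to real-world EEG
artifacts.

## Two generation paths

Cohort-scale analyses generate band-limited trials directly on the 40 Hz
analysis grid ("epochs mode"): the latent model is defined on that grid,
and synthesising 489 full 500 Hz recordings only to low-pass and decimate
them again would dominate runtime without changing what is being tested.
The full-rate path (continuous 500 Hz recording -> notch/high-pass/low-pass
-> downsample -> epoch) is implemented, used by the preprocessing driver
and tests, and checked against the direct path; agreement is strong but not
perfect because the 1 Hz high-pass removes genuine near-DC content of wide
template bumps and slow AR fluctuations.

## Numerical choices and degenerate inputs

* Zero-phase (forward-backward) filtering throughout: the filter families
  and orders are fixed, phase handling is our choice; causal filtering
  would shift ERP latencies, which matters for a time-resolved statistic.
* Epochs are half-open [-1, 1) with 0-based sample indexing: exactly 80
  samples at 40 Hz, event at sample 40.
* AR windows: 8 samples / 7 transition pairs, step 1 sample; pairs never
  straddle a window edge; a window is *missing* (never extrapolated) if it
  has fewer than 50 pooled pairs or a second-moment condition number
  above 1e10. OLS has a known small-sample downward bias; at 150+ trials
  it stays well inside the 0.05 recovery envelope the tests enforce.
* Condition cells need at least 6 trials (`min_trials`) to contribute to
  ERPs or residual pools; a participant with no usable cell is excluded
  with an explicit error.
* PCA sign convention: each weight column's largest-magnitude channel is
  positive. Sign flips would otherwise propagate harmlessly to residuals
  (AR eigenvalues are invariant) but make latent trajectories
  irreproducible across runs.
* Random-effect structures that cannot be identified (categorical-age
  slopes with three visits per participant) fall back in a documented
  order — interaction slopes, then slopes, then intercept-only — and the
  structure used is recorded in the fit object.
* Mediation with a mediator perfectly collinear with the exposure is
  unidentified; the implementation resolves it as full mediation (direct
  effect 0), which keeps the c = c' + ab identity intact.
* BCa intervals for a *null* indirect effect are conservative (the product
  a·b has excess mass near 0 under the joint null), so empirical coverage
  sits at or above the nominal 95%; the calibration test asserts coverage
  >= 0.92 with no upper bound for this reason.

## Open choices made here (the source design left them open)

* The staircase's start (400 ms), bounds ([50, 1000] ms) and the role of
  practice trials (staircase warm-up, cumulative accuracy resets before
  the test block) are configurable defaults.
* BIS standardization stratum: across participants within age x
  condition; the BIS formula is z(accuracy) - z(RT) with equal weights,
  RT summarized over correct trials only.
* The FDR family is time points within one effect and one alignment;
  clusters are defined on FDR-adjusted significance.
* The eigenvalue-BIS model and the mediations use cluster-averaged
  eigenvalues (age-effect clusters for the age pathway, group-effect
  clusters for the institutionalization pathway); timewise BIS models are
  available via `timewise_test(..., model = "bis")` but are not part of
  the default pipeline budget.
* Problem sizes used by the shipped analysis: the full default cohort
  (163 participants x 3 visits, 160 test trials each) for the state space,
  dynamics and statistics; 200 sessions for staircase calibration; 500
  replicates (1000 bootstrap draws each) for null-coverage calibration.

## Known limitations

* Two latent dimensions are assumed throughout, as in the analysis this
  package implements; the PCA stage reports all eigenvalues so a violation
  would be visible, but nothing downstream adapts to it.
* The AR fit pools all condition cells; condition-specific dynamics would
  be aliased into the pooled estimate.
* Recovery guarantees are Monte-Carlo statements at the default noise
  levels; much lower SNR (sensor noise comparable to latent residual
  scale) attenuates eigenvalue estimates (classical errors-in-variables
  bias), and the generator's defaults deliberately sit away from that
  regime.
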