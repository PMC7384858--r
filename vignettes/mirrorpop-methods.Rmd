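---
title: "Methods: population analyses of grasp execution, observation and withholding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population analyses of grasp execution, observation and withholding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`mirrorpop` implements a population-analysis pipeline for motor-cortical
(M1, F5) spiking data recorded in a Go/NoGo reach-to-grasp task with three
conditions — action execution, action observation, and movement withholding
(NoGo) — and two grasps (precision grip, PG; whole-hand grasp, WHG). The
pipeline covers: spike preprocessing into multi-event aligned,
soft-normalized rate tensors; EMG-based gating of passive trials;
single-unit mirror-neuron (MN) classification; cross-condition epoch and
cross-temporal correlations with shuffle nulls; PCA subspace fitting with a
variance-alignment index tested against random-orthonormal nulls and
neuron-subsample bootstraps; and pseudo-population decoding with a
maximum-correlation classifier and a consecutive-bin cluster rule. A seeded
synthetic-session generator with planted ground truth supports calibration
and parameter-recovery testing throughout.

## The data model

A session is a `session_bundle`: a neuron table (area M1/F5, identity
PTN/UID — M1 splits by antidromic identification, F5 pools both), a list of
trials (condition, grasp, outcome, event map over LCDon, ObjCue, GoNogo,
HPR, DO, HO, HOFF, HPN, per-neuron spike-time lists), and an optional EMG
block (up to 12 muscles). All times are milliseconds on one session clock;
error trials are excluded from every analysis. The native store is a single
JSON document plus a CSV event-table export — an HDF5 layout was considered
but no HDF5 binding is available in the target environment, and the session
sizes involved do not need one.

## Preprocessing

Spike counts in 10 ms half-open bins (`[t, t + 10)`; a spike on a boundary
belongs to the bin starting there) are converted to spikes/s and smoothed
with a unit-area Gaussian kernel (SD 50 ms, truncated at ±4 SD and
renormalized; edges renormalize the kernel over its valid support so
constants are preserved).

Because event timing varies across trials, rates are averaged three times —
aligned to the Go cue, to homepad release (HPR), and to displacement onset
(DO) — and stitched on a canonical timeline with Go = 0 and HPR/DO at their
session-mean times (means across execution and observation trials of both
grasps). Each canonical segment is owned by its nearest event, with
boundaries at the midpoints between canonical event times. The source
procedure says only that per-event PSTHs were "interpolated" into one
continuous trace; we resolve this with a 100 ms linear crossfade across
each boundary, which is exactly continuous and reduces to the plain
single-aligned average when all trials' events already sit at the canonical
times. NoGo trials, having no movement events, are singly aligned to the
cue. Trials missing a required event are skipped with a warning, never
imputed.

Baseline correction subtracts, per neuron, the mean rate in the 250 ms
before LCDon averaged across conditions; negative values then indicate
suppression. Soft normalization has two modes: `range_soft` divides by the
neuron's firing-rate range across all times and conditions plus 5 spikes/s
(used for heatmaps, population averages and subspace analyses), and
`absmax_soft` divides by the maximum absolute epoch-averaged rate plus 5
(used for the epoch correlations). The +5 constant bounds outputs strictly
inside (−1, 1) and damps low-firing neurons; a silent neuron maps to zero.

Canonical epochs: the ANOVA set (Baseline: LCDon→ObjCue; Reach: HPR→DO;
GraspHold: 0–700 ms from HO) and the eight correlation periods (PreLCD,
Pres, ObjectCue, EarlyReact 0–150 ms, LateReact 150–300 ms, Early/LateReach
as the per-trial halves of HPR→DO, Hold 0–700 ms from HO). Reaction time is
Go→HPR, movement time HPR→DO.

## EMG gating

Envelopes are computed by rectifying the raw trace and band-pass filtering
at 0.5–30 Hz with a zero-phase 4-pole Butterworth. With no signal-processing
package available in the target environment, the Butterworth design
(bilinear transform of the analog prototype) and forward–backward filtering
are implemented here and validated in the tests against independently
computed reference coefficients. Two implementation details matter:

* "4th-order band-pass" is read as a 4-pole overall filter (prototype
  order 2), the usual convention when a band-pass order is reported.
* the padding for zero-phase filtering is scaled to ~6 times the slowest
  pole's time constant. A 0.5 Hz corner has a ~0.3 s transient; with the
  textbook short padding, start-up transients systematically bias the
  baseline-interval envelope and miscalibrate every downstream test.

Noisy channels (mean execution Reaction envelope not exceeding baseline —
a working electrode must see the execution burst) are dropped per session.

Contaminated-trial exclusion iterates: per muscle, a one-sided test asks
whether Reaction-interval EMG exceeds baseline-interval EMG across the
remaining trials; while any muscle is significant (family-wise α = 0.05,
Bonferroni over muscles), the trial with the largest mean Reaction envelope
on the most-significant muscle is removed and all muscles re-tested. Three
statistical choices here are ours, and deliberate:

1. **Samples are 100 ms block means** of the envelope, pooled across
   trials, so the two intervals contribute *unequal* sample counts (the
   Reaction interval is longer than the 300 ms baseline) — our reading of
   an "unbalanced" two-sample comparison. Testing per-trial interval means
   instead makes the procedure provably blind to its own target: with k
   strongly contaminated trials among ~30, the t statistic saturates near
   √k (≈1.7 for k = 3) because the outliers inflate the sample variance,
   so the removal loop never triggers.
2. **The denominator uses baseline-interval variability only**
   (df = n_baseline − 1). Under the null both intervals share a variance,
   so the test stays calibrated; under contamination the Reaction variance
   is inflated by the very outliers under test.
3. **One-sided, Bonferroni-corrected.** Contamination can only raise EMG;
   and without a family correction across 12 muscles, roughly half of all
   clean sessions would trigger at least one removal, versus the observed
   behaviour that most real sessions lose no trials.
4. **An across-muscle Stouffer-pooled statistic joins the family**
   (Bonferroni over muscles + 1). Genuine movement leakage recruits many
   muscles a little; in simulation, the last mildly contaminated trial of
   a session routinely elevated every muscle without any single muscle
   reaching its corrected threshold. When the pooled test leads, the
   removed trial is the one with the largest across-muscle z-scored
   Reaction mean.

With this design, simulated clean sessions lose essentially no trials and
planted contamination at 5 baseline-SD is removed reliably (see the
acceptance suite). Downstream floors: units need ≥10 observation trials
per grasp, and ≥7 NoGo trials per grasp for NoGo analyses.

Trial EMG distances z-score each muscle's interval mean against the
baseline mean/SD across trials and take the Euclidean norm over muscles;
under the null these follow a chi distribution with one degree of freedom
per clean muscle. The EMG median split divides each grasp's trials at the
median Reaction distance (computed before any exclusion); odd counts put
the median trial in the low half, ties break by trial index.

## Single-unit classification

Per condition, trial-level epoch mean rates (spikes/s — epochs have unequal
durations, so rates, not counts) enter a 2-way ANOVA with factors EPOCH
(Baseline, Reach, GraspHold) and GRASP, followed by post-hoc paired t-tests
of each task epoch against baseline per grasp (uncorrected at α = 0.05 by
default; a Holm flag is provided). A unit is task-modulated when the epoch
main effect or interaction is significant and at least one post-hoc test
is; units modulated in both execution and observation are MNs. The ANOVA
uses sequential sums of squares with EPOCH first; the calibration tests use
balanced designs, where all SS types coincide. MN categories (F-F, F-S,
S-F, S-S per grasp) take the sign of the largest |epoch − baseline|
deviation over Reach and GraspHold in each condition; exact ties resolve to
Reach. Categories are invariant to adding a constant to all epochs.

## Correlation analyses

For each epoch the execution and observation population vectors (length
N neurons × 2 grasps, absmax-soft-normalized) are Pearson-correlated, with
a parametric p-value and a shuffle null: 1000 permutations of the
observation vector (destroying within-unit pairing), significance when the
observed r exceeds the null's 95th percentile. The default shuffle permutes
the full N·C vector; a within-grasp variant is available by flag. Undefined
correlations (zero variance) propagate as missing, never as zero. The
cross-temporal matrix correlates the execution population vector at each
50 ms bin with the observation vector at every bin — unsmoothed bins, since
kernel smoothing would induce trivial short-lag correlations — in both
orders, averaged with its transpose ("averaged across the diagonal" is read
as symmetrization: M(t1,t2) with M(t2,t1)).

## Subspace analyses

For a T×N activity matrix (soft-normalized, per condition and grasp,
centred per neuron over time) the subspace is the top-k (k = 3)
eigenvectors of the covariance across neurons, with deterministic sign
(largest-|entry| coordinate positive). The alignment of target activity in
a reference subspace is

a = tr(Vᵀ C V) / Σᵢ₌₁..k λᵢ(C),

with C the target covariance and V the reference basis: the variance the
reference axes capture in the target, normalized by the most any k axes
could capture. a ∈ [0, 1]; it is invariant to global rescaling of the data
and to the covariance denominator convention (T vs T−1 cancels). Windows:
the movement subspace is fit on execution activity from HPR−50 ms to
HO+500 ms; the observation subspace on observation activity 100–400 ms
after the Go cue, with execution and NoGo projected into it.

Significance uses a null of 10,000 Haar-uniform random orthonormal N×k
bases (QR of a standard Gaussian matrix with sign correction), with
p = proportion of null alignments *strictly greater* than the observed
value (resolution 1/10,000). For rank-k equal-eigenvalue targets the null
mean is k/N. Subspaces are fit per grasp; cross-grasp similarity is
compared between conditions by bootstrap: 1000 draws of 50% of the neurons
(without replacement), fitting one grasp's subspace and projecting the
other on the identical neuron subset within each condition, with the
one-sided p the proportion of execution draws exceeding their paired
observation draws. Rank-deficient subsets are discarded and redrawn, with a
count kept. Statistics use k = 3 even where trajectory plots would show 2
dimensions. A covariance-constrained alternative null was deliberately not
implemented (it is biased towards reporting orthogonality).

## Decoding

Pseudo-populations combine non-simultaneously recorded units: per unit, 10
randomly drawn trials per condition, spike counts in 50 ms bins singly
aligned to the Go/NoGo cue, giving 30 labelled points per unit for the
three-way problem (pairwise variants drop a condition). Units below 10
trials in any requested condition are excluded. Per bin: features are
z-scored with training-fold statistics only; the maximum-correlation
classifier assigns each test vector the class whose mean training vector it
correlates with best (ties to the earlier class; a vector with no variance
after z-scoring is undefined and scored incorrect). Accuracy is 10-fold
cross-validated (splits balanced per class) and averaged over 50 resampled
split assignments. The permutation null repeats the identical procedure 50
times with labels shuffled before splitting; a bin is pointwise significant
when its accuracy exceeds *all* null values (minimal attainable p ≈ 1/50),
and reported significant only within runs of ≥5 consecutive significant
bins. The inner CV loop is a vectorized implementation verified in the
tests to match the reference classifier fold-for-fold.

## The synthetic generator

`generate_session()` draws, per condition c, an orthonormal loading basis
W_c (N × k, k = 3 by default) and builds rates
λ(t) = max(0, b + g_c · A · √N · W_c z(t)): per-neuron lognormal baselines
b (median 8 spikes/s), condition gains g (observation 1/3.5 of execution —
the population-average execution/observation amplitude ratio — NoGo 0.25),
and latent trajectories z made of Gaussian bumps anchored to each trial's
Go/HPR/DO events (Go-anchored only for NoGo), so multi-alignment has
event-locked structure to recover. The √N factor makes `amplitude` the
*per-neuron* modulation depth (default 15 spikes/s), independent of
population size; without it, larger simulated populations would have weaker
single-neuron tuning, which is unphysiological. Rectification at zero is
the simplest positivity guarantee; mixed-sign loadings let
suppression-type responses arise naturally. Spikes are inhomogeneous
Poisson at 1 ms resolution.

Subspace sharing is planted exactly: W_obs = cos θ · W_exe Q + sin θ ·
W_perp Q′ with θ = arccos(√ρ), so every principal angle between the
execution and observation loading subspaces is θ and, for isotropic
latents, the alignment of one condition in the other's subspace is ρ. The
observation↔NoGo overlap knob is analogous (it is a testing construct, not
a claim about the recorded data — no generative model of NoGo activity is
given by the source).

Event times are lognormal with medians from the reported behaviour
(execution RT 310 ms, MT 306 ms; observation uses the slower experimenter
timing, RT 442 ms, MT 430 ms) and CV 0.12 — the source reports
session-median dispersions, not trial-level SDs, so the trial CV is our
choice of a typical well-trained-monkey value. EMG is white noise per
muscle with an execution-only burst (amplitude 4× baseline SD between Go
and DO), random per-muscle gains, an optional count of dead (flat-zero)
channels, and per-trial lognormal amplitude gain (sdlog 0.2) modelling
electrode/posture nonstationarity; setting it to zero gives the exact
stationary null used by the chi-distribution oracle test.
`inject_emg_contamination()` adds a Reaction-window burst scaled in
multiples of the trial's baseline-sample SD to chosen passive trials and
records the ground truth.

What the generator does *not* emulate: correlated (non-Poisson) spiking
noise, session-to-session heterogeneity, kinematic structure in EMG beyond
a single burst, eye movements, and any specific relation between latent
geometry and cell identity. A green acceptance test therefore establishes
that the *analyses* behave as specified on data with the planted
statistical structure — not that the biological claims of any particular
dataset are reproduced.

## Calibration choices in the acceptance suite

* The cos²θ recovery test runs in a high-baseline (100 spikes/s), moderate
  amplitude regime where rectification never clips: clipping bends the
  planted direction and the criterion targets the alignment estimator, not
  the rectifying rate model. It also runs on un-normalized rates, since
  per-neuron soft normalization rescales coordinates and (by design)
  distorts planted angles; the estimator itself is scale-invariant.
* Null-distribution checks use rank-k equal-eigenvalue targets built
  exactly (orthonormal time courses), where the Haar-null mean is k/N.
* The M1-like/F5-like signature tests use the recorded M1-PTN population
  size (59 neurons) and, like the cos²θ test, a linear rate regime
  (baselines well above the modulation depth). At low baselines,
  rectification clipping of passive-condition rates injects a shared
  nonlinear distortion direction across conditions that both fakes and
  masks subspace overlap — a caveat that applies to the alignment method
  on real data whenever firing-rate floors bind.
* The decoder null-calibration runs use fewer bins than a full session
  timeline (the cluster rule depends only on consecutive-bin counts), to
  stay inside the runtime budget; permutations, resamples and splits are
  at their stated defaults.

## Known limitations

* The deposited-data adapter reads a documented CSV export rather than the
  original MATLAB structures (no .mat reader is available offline), so
  external-reproduction checks require converting the deposit once.
* The multi-alignment crossfade is one defensible reading of
  "interpolated"; concatenation at fixed offsets without blending would
  differ within ±50 ms of the stitch boundaries.
* Pointwise decoding significance at 50 permutations cannot produce
  p < 1/50; the permutation count is configurable upward.
* The Spearman variant of the epoch correlation is provided but untested
  against any reference.
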