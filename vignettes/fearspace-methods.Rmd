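---
title: "Methods: searchlight cross-decoding of conditioned and phobic fear"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: searchlight cross-decoding of conditioned and phobic fear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fearspace)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, the numerical choices that were genuinely open,
and what the synthetic benchmarks do and do not establish about real data.

## The scientific question

Pavlovian conditioning pairs a neutral stimulus class (CS+) with an aversive
shock. If the brain encodes an abstract *state of fear* — shared between a
freshly conditioned fear and a pre-existing phobia — then after conditioning
the CS+'s multivariate activation pattern should move toward the pattern of
a phobic stimulus class (PS) and, after extinction, back. The package asks
this question with a cross-decoding design: a classifier trained to
discriminate a neutral class (NS) from PS is applied to CS+ patterns at each
experimental phase, and the voxel-wise probability of labeling the CS+ as
phobic should follow a low/high/low (inverted-U) trajectory over baseline,
conditioned and extinction phases wherever such shared fear information
lives.

## Experimental design emulated by the generator

`design_config()` encodes the session: 8 runs (2 baseline, 1 conditioning, 3
conditioned, 2 extinction). Standard runs present 6 images × 2 repetitions ×
3 classes = 36 trials; the conditioning run omits PS (24 trials). Class
order is pseudorandomized by rejection sampling (10,000-attempt cap) so no
class appears more than twice in a row. A trial is 2 s fixation + 1.5 s
stimulus + an inter-trial interval of 6 + X s, X ~ geometric(p = 0.3)
counting failures before the first success, clipped at 10 s (8 s during
conditioning) — "truncated at" is read literally as clipping, matching the
convention of the stimulus-delivery toolchain this design descends from.
Shocks reinforce 6 of 12 CS+ trials in the conditioning run and 4 of 12 in
each conditioned run, placed uniformly at random among that run's CS+
trials.

## Representational geometry

`representational_geometry()` fixes ground truth. Classes are unit prototype
vectors over the informative voxels; similarity is the angle between them.
Four models describe conditioning: **A** static; **B** θ_p → θ_p − ε₂ (CS+
moves toward PS); **C** θ_n → θ_n + ε₁ (away from NS); **D** both.
Extinction always restores baseline angles, and NS/PS never move.

Prototypes are built exactly, not approximately: a random orthonormal
3-frame is drawn in the informative subspace (QR of a Gaussian matrix), NS
sits on the first axis, PS at θ_np in the plane of the first two, and each
phase's CS+ gets closed-form coordinates realizing (θ_n, θ_p) in the full
3-space. A triple violating the spherical triangle inequality
(|θ_n − θ_p| ≤ θ_np ≤ θ_n + θ_p, per phase) raises an error up front.

Defaults, chosen once:

* θ_n = 40°, θ_p = 60°, ε₂ = 40° (so θ_p: 60° → 20° → 60° under model B),
  ε₁ = 20° where a model needs it. These are large, unambiguous geometry
  changes — the regime the design's logic presumes.
* θ_np = 50° (the NS–PS angle, which only relative geometry constrains): it
  keeps every default model inside the triangle inequality at every phase
  and makes NS and PS comfortably discriminable without being antipodal.
* Grid 20×20×20 with a 5×5×5 informative block and 12 simulated
  participants: large enough for spatial inference to mean something, small
  enough that the full chain runs in minutes on one CPU.
* `signal_amplitude = 3`, `noise_sd = 1`. The per-trial signal-to-noise
  regime is not something the design pins down, so it was calibrated once to
  the stated goal that the NS-vs-PS classifier in an informative searchlight
  work clearly above chance and below ceiling: at these values baseline-phase
  P(CS+ → PS) ≈ 0.3 and conditioned-phase ≈ 0.6 in the block, and ROI
  accuracies run ≈ 0.7–0.8.

`generate_trial_patterns()` emits trial maps = amplitude × prototype
(inside the mask) + i.i.d. N(0, noise_sd²) everywhere. These stand in for
single-trial *t*-maps. `generate_bold()` instead lays the patterns onto a
time axis (HRF-convolved event regressors at the TR grid), adds slow cosine
drift with random per-voxel weights, i.i.d. temporal noise and six smooth
random-walk motion regressors, for end-to-end GLM testing. Not emulated:
spatial autocorrelation (noise is i.i.d. by design; a smoothing hook would
be the natural extension), physiological noise, scanner drift structure
beyond low-frequency cosines, and any between-participant anatomical
variability. Passing tests therefore demonstrate the *chain's* correctness
and calibration under its own assumptions, not robustness to real fMRI
noise structure.

## Single-trial GLM

One gamma HRF — shape (mean/σ)² = 4, scale σ²/mean = 1.5 s (mean lag 6 s,
σ = 3 s, shift φ = 0), sampled at the TR and normalized to unit sum — is
convolved with a per-trial event impulse (onsets rounded to the TR grid;
desk-scale simplicity, documented rather than hidden). All trials of a run
enter one model (least-squares-all): with "single-trial GLMs" underdetermined
between LS-A and LS-S, LS-A is the simpler faithful reading and keeps the
run as the estimation unit that cross-validation folds respect. Six motion
regressors and an intercept are appended; shock CS+ trials keep their own
regressors but are flagged nuisance. High-pass filtering projects out a
discrete-cosine basis (every component with period > 100 s, plus the mean)
from data and regressors alike — equivalent in the passband to the classic
Gaussian-weighted running-line filter but testable in closed form. No
spatial smoothing anywhere. *t* = β̂/SE(β̂) per voxel; voxels with
numerically zero residual variance get a capped ±10⁶ surrogate plus a
warning instead of propagating NaN.

## Searchlight cross-decoding

Neighborhoods are the 50 nearest in-mask voxels by Euclidean index distance
(ties broken by linear voxel index, so results are deterministic);
nearest-count rather than fixed-radius keeps edge neighborhoods full-sized.
The classifier is a two-class LDA with pooled within-class covariance shrunk
as Σ + λ·mean(diag Σ)·I. λ = 0.01 (exposed in the configuration) — some
regularization is necessary because 50 voxels approaches the per-class
sample count in a fold; the value follows the convention of the MVPA
toolboxes this analysis style comes from. Folds hold out one of the seven
analyzed runs; training pools NS and PS trials from the other six
(conditioning-run data are never used); test trials are the held-out run's
non-shock CS+ trials. "Probability of classifying CS+ as PS" is the hard
label fraction, not a posterior — the literal reading, and the one the
toolchain uses. Per-phase maps average the folds whose held-out run belongs
to that phase (CS+ test samples exist only in the held-out run, so no other
aggregation is possible).

## Group inference

With three phase values per voxel, the quadratic fit at codes (−1, 0, +1)
interpolates exactly: a = (y₁ + y₃)/2 − y₂. The coding is symmetric integer;
orthogonal-polynomial coding would rescale *a* by a constant and cannot
change its sign or any test outcome. An Anderson–Darling screen
(`nortest::ad.test`, α = 0.05, 10,000 sampled voxels) checks that
participant vectors of coefficients are compatible with normality before
t-based inference.

One-sample t maps (one-tailed: the hypothesis predicts a < 0) are corrected
by sign-flip resampling: each iteration negates a uniformly-drawn nonempty
subset of participants' coefficient maps, recomputes the t map, applies TFCE
(E = 0.5, H = 2, dh = 0.1, 26-connectivity by default; 6 and 18
configurable) to the tail-oriented map, and stores the volume-wise maximum.
Two deliberate choices here:

* **The flipped subset is never empty.** Drawing k from {0, …, n} would let
  k = 0 reproduce the observed map exactly, so roughly 1/(n+1) of null draws
  would tie the observed maximum and every voxel's empirical p would be
  bounded below by ≈ 1/(n+1) — 0.077 at n = 12 — making small family-wise p
  values structurally unreachable. k is therefore uniform on {1, …, n}; the
  independent coin-flip scheme (uniform over all sign patterns) is available
  as `scheme = "coin_flip"`, and the two agree closely in practice. The
  empirical family-wise error rate of the default scheme under a global null
  sits at the nominal 5% level (checked by simulation in the test suite).
* **Empirical p uses the +1/+1 convention**, p = (b + 1)/(m + 1), keeping
  p ≥ 1/(m+1) > 0.

Corrected p maps are converted to z via the inverse survival function,
binarized at z = 2.5758 (p < 0.005) and segmented into clusters; each
cluster reports size, peak voxel, signed peak statistic, p and z(p). The
desk-scale default is m = 1000 iterations (the full-scale convention is
10,000); with m = 1000 the smallest attainable p is ≈ 0.001, ample for the
0.005 threshold.

## Similarity analysis and model adjudication

Around a surviving cluster's peak, patterns are averaged per cell (NS and PS
pooled over analyzed phases, CS+ per phase; shock trials excluded), then
detrended by removing the best-fit line over voxel index — the default
detrend of the numerical environment this analysis style originates from;
mean-centering alone and no detrending are available
(`detrend = "center"` / `"none"`, the latter used for exact geometry
round-trip tests). Cosines cos∠(NS, CS+) and cos∠(PS, CS+) per phase and
participant feed two group-level tests on Δθ = θ(conditioned) − θ(baseline)
(angles via arccos); the verdict is **B** if θ_p shrank significantly while
θ_n did not move, **C** for the converse, **D** for both, **A** for neither.

For the correlation follow-up, cosines and decoding probabilities (the
latter rescaled by 2p − 1 first) are Fisher-transformed (atanh, inputs
clipped at ±(1 − 10⁻⁷)) and pooled over participants × phases
(n × 3 points — the pooling consistent with the degrees of freedom this
style of analysis reports; per-participant correlation is a one-line
variation). Significance uses a family-wise threshold of 0.005, read as
Bonferroni 0.05 over ten region-by-cosine tests. Whether the decoding value
entering the correlation is the region's peak voxel or the region mean is
configurable (`region_value`); peak is the default since the similarity
analysis is anchored at peak voxels.

## ROI control analysis

The control asks whether CS+ vs PS category information in a fixed region
(in practice: higher visual areas) changes across phases. Decoding is
within-phase leave-one-run-out. Because phases contribute unequal run counts
(2/3/2), raw folds would train on different amounts of data — enough, at the
default SNR, to raise conditioned-phase accuracy by ~0.05 purely through
training-set size and masquerade as a phase effect. `roi_decode` therefore
subsamples every fold's training set to the per-class count achievable in
every fold of every phase (here 12 per class), a standard precaution
whenever accuracies are compared across conditions; raw folds remain
available (`train_per_class = Inf`). Accuracies and CS+/PS cosines are
Fisher-transformed before the group tests: per-phase one-sample tests
against chance, and one-way repeated-measures F across phases
(F(c−1, (c−1)(n−1)); a condition effect of exactly zero is reported as
F = 0 even when the error stratum is degenerate).

## Numerical and degenerate-input conventions

* TFCE integrates thresholds h = dh, 2dh, … ≤ max with e(h,v)^E · h^H · dh;
  voxel inclusion uses a 10⁻¹² tolerance so grid values landing exactly on a
  threshold are counted. The implementation (C++ flood fill) is tested to
  1e-9 against an explicit threshold-loop oracle built on igraph.
* Zero-variance voxels in group t maps: capped ±10⁶ surrogate, warning.
* Cosine of a zero-norm vector, empty ROIs or cells, single-class training
  sets, rank-deficient designs, phases without runs, and truncated
  volume/sidecar files all raise immediate errors naming the problem.
* All randomness flows from a single seed (`pipeline_config(seed = )`);
  identical seeds give bit-identical outputs, including the sign-flip null.

## Problem sizes used by the shipped benchmarks

The test suite runs the chain at deliberately small scales: 8³ grids for
decoding properties and error-rate calibration (200 replicate null cohorts,
m = 500 flips), the 20³/5³-block default cohort for the full inverted-U
recovery, and 15 replicate cohorts for the ROI control. These sizes make the
suite run in minutes while keeping every statistical claim a measured one.

## Known limitations

* i.i.d. noise only; no spatial smoothness, so cluster sizes on real data
  will behave differently than in simulation.
* LS-A single-trial estimation collinears badly at short inter-trial
  intervals; the design's ≥ 9.5 s spacing keeps it benign here.
* The similarity stage assumes the informative region is well captured by
  one searchlight around the cluster peak.
* Decoding probabilities are fold-averaged fractions of a handful of test
  trials, hence coarsely discrete at desk scale; the Fisher transform treats
  exact 0/1 by clipping.
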