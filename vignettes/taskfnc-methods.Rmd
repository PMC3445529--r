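---
title: "Methods: group ICA, network connectivity and mediation for task fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group ICA, network connectivity and mediation for task fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models the package implements, the tunable
parameters and their defaults, what the synthetic-study generator does and
does not emulate, and the numerical and design choices made where the
methodology left them open. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The task model

The delayed item recognition trial has three phases: stimulus (a set of 1,
3 or 6 letters shown for 3 s), retention (7 s), and probe (a single letter,
answered within a 3 s window). Crossing load with phase gives the nine
regressors of interest. Each phase is a rectangular epoch — the probe epoch
lasts exactly as long as that trial's response time, so slow responses
carry more probe signal — built on a microtime grid of `TR/microtime`
seconds (default TR = 3 s, microtime = 16, the common convention),
convolved with the canonical double-gamma HRF, and sampled at scan onsets.

The HRF is the difference of two gamma densities: shape 6, scale 1 s for
the response (mode at 5 s) minus one sixth of shape 16, scale 1 s for the
undershoot, evaluated on [0, 32] s and scaled to unit peak. Temporal
derivatives and parametric modulators are out of scope.

Incorrect and timeout trials contribute all three of their phase epochs to
a single nuisance regressor and are excluded from every downstream measure;
the timeout probe epoch uses the full 3 s response window because no RT
exists. (Whether error trials' probe epochs should instead use the
erroneous RT is undocumented in the source methodology; the full-window
choice is deliberately conservative and configurable via the event table.)
Task columns are mean-centered within run so per-run intercepts absorb the
baseline.

Six contrasts summarize each component's task relationship: within each
phase, a *load-dependent* contrast with weights proportional to the
centered loads ((-7/3, -1/3, 8/3)/norm, unit Euclidean norm — a
linear-in-load "slope" coding, chosen because the load levels are
quantitative; no canonical weighting is prescribed anywhere) and a
*load-independent* contrast (1/3, 1/3, 1/3). Dependent and independent
contrasts are orthogonal within phase.

## Group spatial ICA

Dimension reduction is temporal PCA (the scans-by-scans covariance across
voxels), computed by SVD of the data matrix and cross-checked against a
dense eigendecomposition in the tests. Stage one reduces each run to 30
components (default); stage two stacks all subjects' and runs' whitened
reductions (subject-major, run-minor) and reduces to the model order. The
stacking is a single pooled second stage — whether the original GIFT-style
analysis interposed a per-subject reduction is ambiguous, and the pooled
form is the simpler default. Model order is a configuration parameter
(36 in the motivating study; 6 in the synthetic defaults, matching the
planted sources); order estimation (MDL) is out of scope.

Infomax ICA maximizes output entropy through a logistic nonlinearity with
natural-gradient updates over random-permutation mini-batches
(block size `floor(sqrt(voxels/3))`, initial rate `0.00065/log(n)` — the
hyperparameters commonly used in fMRI practice). When weights blow up the
rate anneals by 0.9 and the iteration restarts from identity; the rate also
anneals when successive updates decorrelate (angle above 60 degrees) or
once the update norm is already small, so the update norm decays
geometrically and convergence (Frobenius norm of the per-pass update below
1e-6, at most 512 passes) is reached deterministically. Non-convergence is
flagged in the result, not thrown. Sources are scaled to unit variance with
the largest-magnitude voxel of each map made positive; this sign
convention is idempotent.

ICASSO runs the decomposition `n_reps` times (20 by default) from distinct
derived seeds — seed repetitions only, no voxel resampling — pools all
estimates, clusters them by average linkage on `1 - |r|` between maps, and
keeps each cluster's centrotype. The stability index
`Iq = mean intra-cluster - mean extra-cluster similarity` is near 1 for
components recovered identically in every repetition.

Back-reconstruction follows the GICA convention: a subject-run's time
courses compose the run dewhitening operator, that run's partition of the
group dewhitening operator, and the ICA mixing matrix; spatial maps apply
the pseudo-inverse of the composed mixing to the run's reduced data. Dual
regression is available behind `flavor = "dual_regression"` and agrees with
GICA on noiseless phantoms.

Visual artifact screening is replaced by two documented rules: a component
is flagged when its peak absolute weight falls outside the eroded mask
interior, or when the average fraction of its time-course spectral power
above 0.1 Hz exceeds a threshold (default 0.5; hemodynamic task responses
at these trial durations live well below 0.1 Hz). The flagged list can be
overridden in configuration, preserving the analyst's prerogative.

## Task relatedness and network connectivity

Each back-reconstructed component time course is fit by OLS against the
run-blocked design; contrast-weighted betas enter one-sample within-group
tests (value ~ intercept + centered gender; the intercept t, df = n - 2)
and between-group tests (value ~ intercept + group + centered gender),
oriented so positive t means young exceeds old. A component is task-related
if any contrast is significant in either group under Bonferroni correction.
The family defaults to (non-artifact components) x 6 contrasts x 2 groups
— with 25 non-artifact components this gives the 300 comparisons quoted in
the motivating analysis, whose exact family composition was never printed;
the family size is recorded with every decision and configurable.

FNC is the Pearson correlation between component time courses within
subject, computed after demeaning each run separately (inter-run offsets
would otherwise masquerade as connectivity), Fisher z-transformed with |r|
clipped at 1 - 1e-12 so perfect correlations stay finite. Zero-lag
correlation is used as stated, not the lagged variant. Constant time
courses yield masked edges, excluded pairwise with counts reported. Edge
tests reuse the between-group machinery with the family equal to the number
of component pairs; components with no significant edge are pruned.
Edge-performance regressions (sRT on z plus centered gender) use the
significant-edge count as their family.

## Behavior and structure

Per-load median RTs use correct, responded trials only. sRT is the OLS
slope of the three medians against the raw loads (1, 3, 6) — "seconds per
letter", matching the set-size interpretation. d_L is the logistic
discrimination index `ln[H(1-FA)/((1-H)FA)]` with the 0.5/(n+1) log-linear
correction; the methodology names d_L without printing a formula, and this
is its standard form (the correction choice is configurable by supplying
counts directly). nWBV is (GM+WM)/(GM+WM+CSF) from supplied tissue volumes.

## Mediation

Paths come from three OLS fits sharing the covariate set (centered gender),
so `c = c' + a*b` holds to machine precision and is asserted in the tests.
The bootstrap is stratified: each replicate resamples within age group,
preserving both group sizes exactly, and recomputes `a*b`. Intervals are
bias-corrected percentile (BC, no acceleration — "bias-corrected
percentile" names BC; BCa would need a jackknife acceleration estimate and
is deliberately not implied): `z0` is the normal quantile of the fraction
of bootstrap values below the point estimate, ties counted half, degenerate
fractions clamped to 1/B from the boundary; endpoints are bootstrap order
statistics at the adjusted percentiles using the (B+1)p convention
(`quantile` type 6). Significance is the interval excluding zero. Default
B = 10,000; calibration simulations in the tests and acceptance script use
B = 1,000 with 1,000 (coverage) and 500 (type-I) simulated studies — sizes
chosen so the Monte Carlo error on a 95% coverage estimate is about 0.7
percentage points.

One printed inconsistency in the motivating report is deliberately not
reproduced: its path products (a x b) do not equal its printed indirect
effects. This package reports the indirect effect as the product of the
point-estimate paths, which is the quantity its bootstrap resamples.

## The synthetic-study generator

The generator is the package's validation instrument, not a data model of
real MRI. It emulates: 75 young + 37 old subjects (gender ratios 50:25 and
15:22), 3 runs x 69 scans at TR = 3 s; compact Gaussian-blob sources
(pairwise spatial |r| < 0.2 by placement) with unit-variance maps — the
sparse maps are super-Gaussian, keeping infomax separation well-posed — and
Laplace residual innovations; group-specific residual correlation matrices
(edge 1-2 planted at r = 0.514 young / 0.059 old, edge 3-4 at
0.448 / 0.113, all other edges 0.1, subject z values varying with sd 0.15);
per-trial RTs `intercept + slope x load` truncated to (0, 3] with the
subject slope coupled to the planted edge
(`slope = group slope + kappa (z - young mean z)`, kappa = -0.15, so weaker
connectivity steepens the load cost); hit/false-alarm rates 0.80/0.25
giving d_L near 2.4; and lognormal tissue volumes whose group means put
nWBV near 0.85 (young) and 0.71 (old) while staying conditionally
independent of connectivity given age group — the volume path is a planted
*non*-mediator.

Two documented departures from the emulated study's surface numbers:

* Each run holds 4 trials per load (12 trials), not 10 per load. Thirty
  trials of at least 13 s cannot fit in a 69-scan (207 s) run; the scan
  count is kept and the trial count reduced, configurable via
  `trials_per_load_per_run`.
* The old group's RT regime is anchored to the mediation path scale (total
  group slope difference near 0.11 s/letter: direct 0.042 plus transmitted
  0.068) rather than to the printed old-group medians, which imply a
  smaller total difference; the two anchors are mutually inconsistent in
  the source report and the causal structure is the one under test.

Task loadings are deliberately small relative to the residual variance
(per-source task-signal sd at most ~0.3 of the residual sd): large shared
task signal would dilute and distort the planted residual correlations that
downstream stages must recover. Group-level task detection stays strong
because the loadings are consistent across subjects. The generator does not
emulate motion, drift, physiological noise, EPI distortion, spatial
autocorrelation of noise, or anatomical realism — so passing tests certify
the estimators, not robustness to real-world artifacts.

Voxel noise is unit-variance Gaussian against blob peak weights of roughly
5-6, a moderate single-voxel SNR. Connectivity recovery is assessed against
each subject's *realized* time-course correlations (the generator's ground
truth), not the configured population targets: at small voxel counts the
ICA map estimates acquire O(1/sqrt(voxels)) cross-leakage that mildly
attenuates estimated correlations, an effect that vanishes at real-data
voxel counts (hundreds of thousands) but is visible on a 10^3 test grid.

## Problem sizes and runtime choices

The test suite and acceptance script run reduced designs chosen for
informativeness per unit time: ICA recovery on 12 + 12 subjects at a 10^3
grid (spatial |r| > 0.9 required of every source); connectivity recovery on
12 + 12 subjects at the default 12^3 grid (95% of group-mean edges within
0.1 z of the realized truth); 100 replicates for detecting a planted 0.4 z
group difference at n = 75/37; 1,000/500-study calibrations for coverage,
type-I and family-wise error; and a full-size (75 + 37) generator study for
the behavioral, volumetric and mediation estimates. The file-based pipeline
smoke test uses 12 + 12 subjects because task-relatedness classification
under Bonferroni is genuinely underpowered at 6 + 6 — a property of the
statistics, not a defect.

## Known limitations

* Infomax only; fastICA/ERBM variants are out of scope, as are lagged FNC,
  graph metrics and dynamic connectivity.
* The artifact rules are heuristics standing in for expert screening and
  should be reviewed on real data.
* BC (not BCa) intervals; with strongly skewed indirect-effect
  distributions at small n the acceleration term can matter.
* The pipeline assumes equal scans per run and complete runs per subject.
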