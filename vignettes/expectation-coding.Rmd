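---
title: "Expectation-driven encoding of FM-sweeps: models, simulation and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expectation-driven encoding of FM-sweeps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmadapt)
```

# The paradigm and the expectation model

Each trial is a sequence of eight 50 ms FM-sweeps at 700 ms
inter-stimulus intervals (sequence duration `8*50 + 7*700 = 5300` ms):
seven standards and one deviant in position 4, 5 or 6. Two abstract rules
are known to the listener — every sequence has exactly one deviant, and
only positions 4–6 are possible, each used equally often. The resulting
deviant hazard, `prior(k)` renormalised over the positions not yet ruled
out, is 1/3, 1/2 and 1:

```{r}
deviant_hazard(4:6)
```

Three sweeps are used (`default_sweeps()`): fast up (1000 to 1200 Hz), slow
up (1070 to 1170 Hz) and fast down (1280 to 1080 Hz). Their average
frequencies differ so that they are pitch-matched; only FM direction and FM
rate distinguish them. Every ordered standard/deviant pair defines a block;
a run holds all 6 ordered pairs once (6 blocks of 10 trials), and the
|delta f| difference classifies a pair as direction-only (400 Hz),
rate-only (100 Hz) or both (300 Hz).

**Pseudorandomisation.** Deviant positions are balanced within each ordered
pair across the whole experiment (30 per position per pair under the
default 9 runs), which yields 180 trials per position and 60 per
position-by-class cell while leaving per-run counts free, as the design
requires. The shuffle is rejection-free: a balanced multiset per pair is
permuted once and dealt into that pair's block in each run.

**Timing.** The target inter-deviant interval (IDI) is drawn from a normal
distribution (mean 5 s, SD 1 s) truncated to [3, 11] s by inverse-CDF
sampling. The inter-trial interval realising the target follows the
onset-to-onset convention — the deviant onset is `(position-1) * 750` ms
from sequence start — and is floored at 1.5 s, after which the realised IDI
is recomputed. Response-time extensions of the ITI are not modelled (the
default listener responds before the minimum ITI elapses): the extension
rule depends on behavioural timing that the generator does not emulate.
For the same reason the package makes no claim about summary statistics of
the realised IDI/ITI distributions; the construction, not its summaries, is
the contract. The 23 null events per run (silent gaps of one sequence
duration, 5300 ms) are inserted at uniformly random inter-trial boundaries
and never split a trial.

All randomness flows from one integer seed through named substreams (block
order, per-pair positions, timing, null placement, per-run noise), so each
component is independently reproducible and two schedules built from the
same seed are identical.

# Stimulus synthesis

Sweeps are synthesized with a piecewise-linear instantaneous frequency —
constant on the two 5 ms plateaus, linear in Hz across the 40 ms sweep
segment — and the phase is its cumulative integral, so plateau and sweep
merge without discontinuity. Linear-in-Hz chirps follow from the stimuli
being characterised by their frequency span in Hz. Raised-cosine 5 ms
on/off ramps overlap the plateaus and multiply the envelope after phase
synthesis. Default sampling rate is 44.1 kHz and the peak is normalised to
0.9 for headroom on 16-bit export; neither is prescribed by the design, so
both are parameters.

Verification inverts the synthesis: the analytic signal (FFT Hilbert
construction) gives phase increments `Arg(z[t+1] * Conj(z[t]))`, hence an
instantaneous-frequency trajectory. `measure_sweep_span()` fits a line to
the trajectory over the sweep interior (excluding a 3 ms margin against
ramp and edge bias) and evaluates it at the segment boundaries; the three
default sweeps recover their spans within 2 Hz RMS.

# The two response models

Both models are linear in their free amplitudes, so each is a basis matrix
(8 slots x parameters) and fitting always happens by linear regression —
the overall scale is absorbed, which is why the simulator's unit default
parameters are not a tuning knob.

* `h1_basis()`: habituation. `a0` for the first standard; a decay chain
  `a1/n` over pre-deviant standards; full recovery `a2` at the deviant
  regardless of position; a second chain `a3/n` after it.
* `h2_basis()`: precision-weighted prediction error. `a0` for the first
  standard (additionally affected by onset-time uncertainty, hence its own
  parameter); `a1` times the expectation-violation probability elsewhere:
  `hazard(k)` for a standard at candidate position `k`, `1 - hazard(p)`
  for the deviant. Deviants in position 6 elicit zero.

Whether `a0` should be constrained relative to `a1` in h2 is left open by
the model's statement; the two are kept independent here, which is the
weaker assumption and costs one evidence dimension shared by all h2 fits.

# Synthetic BOLD data

A voxel's signal is `baseline + scale * s_m(t) + drift + AR(1) noise`,
where `s_m` places each stimulus as a delta impulse weighted by the
generating model's profile (stimulus duration 50 ms is far below the 1.9 s
repetition time), convolves with the canonical double-gamma HRF (delays
6/16 s, unit dispersions, peak/undershoot ratio 6, peak normalised to 1) at
0.1 s microtime resolution, and samples at volume times. Defaults: noise SD
2 against unit event amplitude (per-event SNR 0.5), AR coefficient 0.3,
first-order polynomial drift with random coefficients (SD 0.5), baseline
100. The phantom is an abstract labelled grid (146 voxels per IC, 152 per
MGB, ventral/dorsomedial tags in the MGBs); no anatomical geometry is
mimicked, and smoothing is a no-op at phantom scale. The true per-voxel
SNR of the measured data is unknown, so `noise_sd` is a free parameter
swept in the tests.

What the generator does *not* emulate: physiological (cardiac/respiratory)
noise structure beyond AR(1), motion, scanner drift nonlinearity,
spatially correlated noise, and behavioural response timing. Passing tests
therefore demonstrate correctness of the inference machinery under the
stated noise model, not robustness to every artefact of real recordings;
nuisance regressors can be appended to the design to represent measured
confounds.

# First-level GLM

The pooled design has 8 condition columns — `std0`, `std1`, `std1xpos`,
`std2`, `std2xpos`, `dev4`, `dev5`, `dev6` — with the parametric modulators
carrying within-sequence positions mean-centred per run and *not*
orthogonalised against their parent columns (orthogonalisation is a
reparametrisation that changes parent-column interpretation; the centred
modulator is the neutral choice). A split-by-class variant provides the 18
per-pair-class columns (6 conditions x 3 classes, no modulators) used for
the direction-only/rate-only partition analyses. Condition columns without
events are flagged and dropped; rank deficiency is an error naming the
collinear columns.

Fitting is ordinary least squares with an optional single AR(1) refit: one
pooled autocorrelation coefficient from the OLS residuals, data and design
whitened, one refit. Betas are z-scored per run and participant; the
normalisation pool is all condition betas across the voxels of the run,
the broadest reading of "per run and participant" and the one that
preserves between-voxel and between-condition structure. Alternative pools
would rescale but not reorder group statistics.

The group test against zero is the two-tailed Wilcoxon signed-rank test
(one value per participant). The design's description of "ranksum tests
(one sample per participant)" is ambiguous between the signed-rank and a
two-sample rank-sum reading; for a one-sample contrast against zero only
the signed-rank form applies, while condition pairs in the group tables
use the two-sample rank-sum test. FDR correction is Benjamini–Hochberg
(step-up) within each anatomical ROI; the SSA p-map is the voxelwise
maximum of the adaptation and deviant-detection p-maps (an upper bound for
the conjunction), FDR-thresholded the same way, and the containment of the
SSA mask in the intersection of its parents is checked and reported.
Volume-matched ROIs select exactly the target count of highest-statistic
voxels inside the (dilated) prior — provably the same set iterative
thresholding converges to — with ties broken by ascending voxel index for
cross-platform determinism. Prior inflation on the phantom grid is binary
dilation by one voxel, the grid-resolution counterpart of a narrow
Gaussian kernel.

# Bayesian model comparison

Per voxel and run, both models are scored by the exact marginal likelihood
of the linear model under a conjugate Normal–Inverse-Gamma prior: zero-mean
coefficients with precision `lambda` scaled by the noise variance, and
Inverse-Gamma(1e-3, 1e-3) on the noise variance. Exactness is preferred
over fidelity to any external variational implementation, and the closed
form is validated against brute-force numerical quadrature to better than
1e-3 nats in the tests.

Three numerical choices matter:

* **Regressor scaling.** Timecourses are standardised per run and each
  model regressor is scaled to unit variance, so coefficients are effect
  sizes in data-SD units and the default `lambda = 1` is weakly
  informative at any SNR. Without this, a fixed prior precision crushes
  coefficients in high-SNR voxels and can invert model attribution — the
  zero-noise recovery invariant is the regression test for this.
* **Shared nuisance.** Intercept and drift columns are appended to both
  designs with a vague precision (1e-6), so evidence differences reflect
  only the condition structure.
* **Serial correlation.** The same pooled AR(1) whitening as the GLM can
  be applied to the data once and to both designs, so the models compete
  on identical data.

Run evidences add across a subject's runs (independent noise, independent
coefficients per run). Subject-level Bayes factors `K = exp(lme_h2 -
lme_h1)` are banded at 10 and 1/10 ("substantial" evidence). The group
analysis is the variational random-effects Dirichlet scheme: subject
responsibilities proportional to `exp(lme + digamma(alpha) -
digamma(sum(alpha)))`, concentrations `alpha = alpha0 + colSums(u)`,
iterated until the concentration change drops below 1e-6 (non-convergence
after 1000 iterations is an error, not a silent result). The prior
concentration `alpha0 = 1` per model and the tolerance are declared
defaults, not inferred from any source. Expected model probabilities are
`alpha/sum(alpha)` and the group K map is their ratio; per-ROI summaries
use kernel-density estimates of log K with Scott's bandwidth.

Because h1 spends four condition regressors against h2's two, the Occam
factor differs between the models by construction (about half a log of the
regressor norm per extra column per run). On pure-noise voxels the
comparison therefore drifts slowly toward the simpler model as runs
accumulate rather than sitting exactly at log K = 0; recovery claims in
the tests are made only for voxels generated under one of the two models,
where fit differences dominate.

# Group statistics

Pairwise condition comparisons use two-tailed rank-sum tests with
Holm–Bonferroni correction over explicitly declared families (12 for the
three deviant contrasts across four ROIs); the family size is a parameter
and supplying one smaller than the number of tests is an error. Effect
sizes are Cohen's d with the pooled standard deviation. The
likelihood-correlation analysis pools per-run region-averaged deviant
responses (3 per run, 27 samples under 9 runs) against the hazards; the
per-run responses are averaged over the region's voxels before
correlating. The subdivision analysis splits any parent mask (e.g. the
ventral MGB against its complement) and compares SI and log K
distributions with two-sample rank tests.

# Problem sizes in the test suite

The suite exercises the full pipeline at sizes chosen to keep a complete
run in minutes while preserving the study's structure: model recovery uses
18 subjects x 9 runs with 20-voxel regions per generating model (plus a
zero-noise cohort where attribution must be perfect in every voxel); FDR
control uses 200 null-phantom replicates of 18 single-run subjects and 30
voxels; the likelihood-correlation mirror uses 50 subjects whose 146-voxel
SSA-region mean is simulated exactly as a single voxel with noise and
drift scaled by `1/sqrt(146)` (the region mean of linear signals with iid
voxel noise); the direction/rate symmetry mirror uses 12 subjects x 3 runs
with the split-by-class design. The reduced block length of 9 trials used
in some fixtures keeps the per-pair position balance at any run count.

# Known limitations

* The habituation decay is fit only in its linear parametrisation; decay
  exponents are not estimated.
* The pooled design's linear position modulators approximate the `1/n`
  habituation decay; at very high effective SNR the approximation error is
  measurable as a small position-dependent bias in the deviant betas
  (without any expectation-like gradient). Magnitude-based checks are the
  appropriate reading of "flat" deviant profiles at simulation precision.
* Exceedance probabilities, family-level inference and model averaging are
  not implemented; expected posterior probabilities summarise the group.
* The localizer and phantom are abstractions: no acoustic confounds, no
  anatomical variability, no coregistration error.
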