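# fmadapt

Simulation and analysis tools for testing whether the subcortical auditory
pathway encodes fast frequency-modulated (FM) sweeps according to the
listener's expectations.

## The scientific problem

In an auditory oddball paradigm, listeners hear trials of eight 50 ms
FM-sweeps: seven repetitions of a *standard* and one *deviant* placed in
position 4, 5 or 6 of the sequence. Two abstract rules are disclosed: every
trial holds exactly one deviant, and it can only sit in positions 4–6, each
equally likely a priori. The conditional probability (hazard) of meeting
the deviant therefore grows along the sequence:

    P(dev at 4 | 3 standards) = 1/3
    P(dev at 5 | 4 standards) = 1/2
    P(dev at 6 | 5 standards) = 1

Blood-oxygen-level-dependent (BOLD) responses in the inferior colliculus
(IC) and medial geniculate body (MGB) are then compared against two linear
response models of the eight per-trial amplitudes:

* **h1 — habituation.** Standards decay asymptotically (`a1/n` after `n`
  repetitions), any deviant recovers the full response `a2` regardless of
  position, and post-deviant standards restart a decay chain `a3/n`. Free
  amplitudes: `a0, a1, a2, a3`.
* **h2 — prediction error.** Responses scale with the probability that the
  heard stimulus violates the current expectation: a standard at candidate
  position `k` elicits `a1 * hazard(k)`, the deviant at position `p`
  elicits `a1 * (1 - hazard(p))` — so a deviant in position 6, which is
  fully expected, elicits none. Free amplitudes: `a0, a1`.

Each voxel's timecourse `y = X b + e` is scored by the closed-form marginal
likelihood under a conjugate Normal–Inverse-Gamma prior (coefficients and
noise variance integrated out), one design per model. Per-subject
log-evidences enter a random-effects group Bayesian model comparison
(variational Dirichlet scheme), yielding expected model probabilities and a
Bayes-factor map `K = P(h2)/P(h1)` per voxel. Stimulus-specific adaptation
(SSA) is quantified by the index

    SI = (dev4 - (std1 + std2)/2) / (dev4 + (std1 + std2)/2)

and SSA regions are the FDR-thresholded conjunction of the adaptation
(`std0 > (std1+std2)/2`) and deviant-detection (`dev4 > (std1+std2)/2`)
contrasts.

Because no human data ship with the package, a synthetic-data module
generates full cohorts (default 18 subjects x 9 runs of 6 blocks by 10
trials, with 23 null events per run) with HRF-convolved responses following
h1 or h2, AR(1) noise plus polynomial drift, and a blocked sound/silence
localizer — so every downstream stage is testable against known ground
truth.

## Worked example

```r
library(fmadapt)

deviant_hazard(4:6)
#> [1] 0.3333333 0.5000000 1.0000000

measure_sweep_span(synthesize_sweep(default_sweeps()$fast_up))
#> [1] 199.9989        # the fast-up sweep spans its nominal 200 Hz

h2_profile(5)
#> <amplitude_profile h2, deviant in 5>
#> [1] 1.0000 0.0000 0.0000 0.3333 0.5000 0.0000 0.0000 0.0000
```

The slot-4 standard carries `hazard(4) = 1/3` of prediction error (a
deviant was expected there with probability 1/3), the slot-5 deviant
carries `1 - hazard(5) = 1/2`.

A reduced end-to-end run (6 subjects, 3 runs, 32-voxel phantom generated
under h2):

```r
cfg <- pipeline_config(n_subjects = 6, runs_per_subject = 3,
                       region_sizes = c("IC-L" = 8, "IC-R" = 8,
                                        "MGB-L" = 8, "MGB-R" = 8),
                       grid = c(4, 4, 2), seed = 7)
rb <- run_pipeline(cfg)

aud <- rb$phantom$region != "background"
mean(rb$rfx$k_map[aud] > 1)
#> [1] 1               # every auditory voxel favours prediction error

round(tapply(rb$condition_summary$value,
             rb$condition_summary$condition, mean), 3)
#>   dev4   dev5   dev6   std0   std1   std2
#>  0.245  0.135 -0.221  0.496 -0.131 -0.223
```

The group-mean z-scored betas show the expectation gradient
`dev4 > dev5 > dev6` with the fully expected `dev6` indistinguishable from
the post-deviant standards — the signature of prediction-error coding that
distinguishes h2 from plain habituation. `rb$comparisons` holds the
rank-test table with Holm-corrected p-values and Cohen's d per ROI, and
`rb$output_dir` contains the event tables, voxel maps and logs as text
files.

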