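Package: fmadapt
Title: Expectation-Driven Encoding of FM-Sweeps: Paradigm Simulation and
    Bayesian Model Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse an auditory oddball paradigm in
    which listeners hold abstract-rule expectations about the position of a
    deviant frequency-modulated (FM) sweep inside short tone sequences.
    Implements the paradigm and stimulus generators (trial sequences,
    deviant-position hazards, phase-continuous FM-sweep synthesis), two
    competing linear response models of subcortical adaptation (habituation
    and precision-weighted prediction error), a synthetic BOLD cohort
    simulator with known ground truth, first-level GLMs with parametric
    modulation and stimulus-specific-adaptation contrasts, volume-matched
    region-of-interest definition, per-voxel conjugate Bayesian model
    evidence with random-effects Dirichlet group model comparison, and the
    accompanying group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
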