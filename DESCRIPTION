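Package: flickerlfp
Title: Sensory Flicker Response Analysis for Intracranial LFP Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies neural responses to rhythmic audio-visual (flicker)
    stimulation in intracranial local field potential recordings.
    Implements Laplacian/bipolar re-referencing of depth-electrode
    recordings, trial segmentation and balancing, multitaper spectral
    estimation with trial-permutation significance of the steady-state
    evoked potential, inter-trial phase-locking values with Rayleigh tests,
    single-pulse evoked potential quantification and the linear-superposition
    counterfactual simulation, spectral parameterization of baseline power
    spectra into aperiodic and oscillatory components for
    resonance/entrainment analysis across a 26-frequency paradigm,
    spike-train vector strength and unit classification, interictal
    epileptiform discharge rate statistics, and distance-weighted anatomical
    label assignment for electrode contacts. Includes a synthetic-session
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    withr,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
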