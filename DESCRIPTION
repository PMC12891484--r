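Package: oscphen
Title: Oscillation Phenotyping of Resting-State EEG and LFP Recordings
Version: 0.1.0
Authors@R: person("Oscphen", "Maintainers", email = "oscphen@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of resting-state electrophysiological
    recordings: multitaper spectral estimation with cross-species
    time-bandwidth calibration, a data-driven Lorentzian decomposition of the
    power spectrum into aperiodic (1/f, with optional knee) and periodic
    components, periodic peak and sub-peak quantification, phase-amplitude
    coupling via the 18-bin modulation index with epoch-shuffled noise
    correction, analytic-envelope burst dynamics with movement-bout
    alignment, and non-parametric hierarchical bootstrap group statistics.
    Includes a synthetic-signal generator with known aperiodic, periodic,
    coupling and burst ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
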