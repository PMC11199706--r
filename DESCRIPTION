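Package: photonup
Title: Quantification of Genetically Encoded Neuropeptide Sensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis toolkit for genetically encoded fluorescent neuropeptide
    sensor data: fractional fluorescence change (dF/F0) quantification with
    membrane ROI selection and photobleaching correction, mono-exponential
    activation/deactivation kinetics with onset-latency gating,
    three-parameter Hill concentration-response fitting (EC50/pEC50), three
    fiber-photometry preprocessing pipelines (power-like baseline dF/F,
    baseline-window isosbestic regression with z-scoring, whole-session
    polynomial detrend plus isosbestic division), and event-aligned epoch
    extraction with per-window z-scores and binned area under the curve.
    Includes forward simulators (two-state ligand binding, two-channel
    photometry sessions with bleaching and motion artifacts, line-scan pixel
    stacks, dose-response plates, behavioral event schedules) that provide
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
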