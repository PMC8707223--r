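Package: synclab
Title: Multistream Clock Synchronization, Offset Calibration and EEG
    Validation by Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation-driven toolkit for validating wearable multistream
    acquisition systems without hardware. Simulates multi-device sessions
    (accelerometer and EEG streams with per-device clock offset, drift,
    jitter, wireless transport latency and packet loss), fits linear clock
    corrections from clock-offset measurement histories and remaps raw
    timestamps onto a shared timeline, estimates residual inter-stream
    transport latencies by cross-correlating accelerometer streams during
    shared mechanical perturbations, and builds pairwise offset matrices in
    milliseconds and samples. Generates synthetic multi-task EEG (alpha
    reactivity, sensorimotor desynchronization, steady-state visual evoked
    potentials, P300 oddball) with injected blinks, lost-sample runs,
    amplitude artifacts and drift, and provides the matching validation
    pipeline: common-average referencing and zero-phase band-pass
    filtering, signal-space projection of blinks, multi-rule epoch
    rejection, Welch and multitaper spectral estimation, Morlet
    event-related spectral perturbation maps, cluster-mass permutation
    statistics, and trial-subsampling statistical power curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'streamsim.R'
    'sessionio.R'
    'syncengine.R'
    'calibration.R'
    'eegsynth.R'
    'preprocess.R'
    'spectral.R'
    'statistics.R'
    'benchmarks.R'
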