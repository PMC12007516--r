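Package: perceptmeg
Title: Simulation and Analysis of DBS Stimulator Interference in MEG Recordings
Version: 0.1.0
Authors@R:
    person("perceptmeg", "developers", email = "perceptmeg@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising the interference that a telemetric
    deep-brain-stimulation pulse generator produces in magnetoencephalography
    (MEG) recordings. Provides a synthetic phantom simulator for three MEG
    system profiles (a 275-channel axial-gradiometer system, a 306-channel
    planar-gradiometer/magnetometer system, and a wearable optically pumped
    magnetometer array) under the stimulator's operating conditions; Welch
    amplitude-spectral-density estimation with bad-segment rejection;
    narrowband peak, harmonic-comb and intermodulation-product detection with
    condition classification; MEG-LFP clock alignment by stimulation toggling,
    transient detection, or ECG cross-correlation; and LFP-referenced
    coherence mapping with a sensor-level permutation test and a DICS
    beamformer on an analytic single-sphere forward model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
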