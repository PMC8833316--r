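Package: megosc
Title: Cortical Oscillation Analysis for MEG: Beamforming, Spectral Power,
    Phase-Amplitude Coupling and Cluster Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for group-level analysis of cortical
    oscillations in trial-epoched magnetoencephalography (MEG) data:
    zero-phase Butterworth filtering and decimation, linearly constrained
    minimum variance (LCMV) beamforming with virtual-electrode extraction,
    multitaper and Hanning time-frequency power with baseline-normalised
    band changes and peak-frequency detection, alpha-gamma phase-amplitude
    coupling via the amplitude-normalised mean-vector-length estimator,
    and cluster-based permutation tests for between-group comparison of
    comodulograms.  Includes a synthetic-cohort generator with known
    ground truth (1/f background, induced alpha suppression, induced
    narrow-band gamma, controllable alpha-phase to gamma-amplitude
    coupling) for end-to-end validation of the analysis chain.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
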