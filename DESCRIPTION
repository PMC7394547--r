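Package: slopetrack
Title: Aperiodic Spectral Slope Tracking of Arousal States in Sleep and
    Anesthesia Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates the 30-45 Hz aperiodic (1/f) slope of EEG/iEEG power
    spectra with multitaper and related estimators, and uses it to separate
    wakefulness from NREM sleep, REM sleep and propofol anesthesia.
    Includes a synthetic polysomnography generator with per-state spectral
    exponents, slow oscillations, spindles, alpha and EMG contamination;
    time-resolved slope tracking; mutual information against the hypnogram
    with block-swap surrogate calibration; slow-wave detection and
    event-locked slope dynamics; permutation and cluster-permutation
    statistics; balanced linear-discriminant classification and a
    general-linear-model variance decomposition; and fronto-parietal
    connectivity controls (coherence, phase locking, orthogonalized power
    correlations).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    MASS,
    car,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
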