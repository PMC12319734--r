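Package: megfingerprint
Title: Cross-Platform MEG Equivalence Analysis via Neural Fingerprinting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for testing whether two
    magnetoencephalography (MEG) platforms -- a wearable triaxial
    optically-pumped magnetometer (OPM) array and a cryogenic SQUID
    axial-gradiometer array -- capture the same individual-specific brain
    signals. Provides a braille somatosensory paradigm generator, spherical
    conductor (Sarvas) forward modelling for both sensor arrays, a synthetic
    cohort generator with subject-stable beta desynchronisation/rebound
    signatures, preprocessing (Welch channel screening, homogeneous field
    correction, reference gradiometry, zero-phase FIR filtering, trial
    rejection), LCMV beamformer pseudo-T imaging and minimum-norm evoked
    imaging, Hilbert-envelope time-frequency spectra, and neural
    fingerprinting statistics (identifiability matrices, permutation nulls,
    sham-mixing group nulls, attentional contrasts, and a chance
    identifiability model).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
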