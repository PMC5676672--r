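Package: bioradar
Title: Wavelet-Entropy Detection of Breathing Targets in Ultra-Wideband Bio-Radar Echoes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing pipeline for impulse ultra-wideband (IR-UWB)
    bio-radar detection of multiple stationary breathing humans, including
    targets hidden in the radar shadow of a nearer person. Implements the
    fast-time/slow-time echo-matrix preprocessing chain (range accumulation,
    sliding-window clutter subtraction, FIR low-pass filtering), per-range
    auto-correlation enhancement of weak periodic respiration signatures, a
    periodized orthogonal discrete wavelet transform, the windowed
    relative-subband-energy Shannon wavelet-entropy statistic, and robust
    entropy-pit detection with torso-width gating and multipath ghost
    rejection. A seeded scene simulator generates echo matrices with wall
    clutter, range attenuation, shadowing cones and trailing multipath so the
    whole chain is testable without radar hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'dwt.R'
    'scene-sim.R'
    'preprocess.R'
    'autocorr.R'
    'entropy.R'
    'detection.R'
    'io.R'
    'pipeline.R'
    'show-methods.R'
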