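Package: sweepvep
Title: Sweep Steady-State VEP Analysis of Binocular Motion Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for sweep steady-state
    visually evoked potential (SSVEP) studies of dichoptic motion.
    Generates multichannel EEG sweep trials with known harmonic structure
    driven by Naka-Rushton displacement response functions, reproduces a
    standard sensor/epoch cleaning chain (bandpass filtering, resampling,
    bad-sensor interpolation, common-average referencing, epoch
    rejection), estimates complex harmonic coefficients per displacement
    bin with a recursive least-squares adaptive filter or windowed DFT
    projection plus sideband noise estimates, learns spatial filters by
    reliable components analysis (a generalized eigendecomposition of
    cross-trial versus pooled covariance), computes complex-domain group
    statistics (vector averages, projected amplitudes, paired t tests),
    and fits Naka-Rushton displacement response functions with an
    anti-phase suppression index.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
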