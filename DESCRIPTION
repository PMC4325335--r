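Package: duoscan
Title: Multi-Site Real-Time fMRI Neurofeedback Simulation and Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale simulator and analysis pipeline for multi-site
    real-time fMRI neurofeedback and brain-computer-interface experiments.
    Generates block-design BOLD volume streams with site-dependent signal
    amplitudes, Gaussian noise and slow drift; performs real-time functional
    localization by growing-window (incremental) correlation after Gaussian
    smoothing; calibrates each subject's signal against the individual maximum
    BOLD response (set to 100%); classifies calibrated activation into
    insufficient / weak (L) / strong (U) bands to drive a virtual object;
    exchanges activation levels and rewards between sites through timestamped
    append-only text files; and orchestrates single, cooperation and
    competition reward tasks, demonstrating that calibrated relative signals
    make sites with grossly different signal amplitudes (e.g. 3T vs 7T)
    comparable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
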