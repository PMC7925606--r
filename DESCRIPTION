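Package: vctbp
Title: Volume Control Technique for Continuous Noninvasive Blood Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the volume control technique (VCT), a slow
    closed-loop contact-pressure controller that tracks mean arterial
    blood pressure from a finger photoplethysmographic (PPG) light
    signal. Provides the digital filter cascade decomposing the PPG
    signal into pulse, rhythm and control components, open-loop
    oscillometric initialization with Gaussian envelope fitting,
    beat-based setpoint control with a continuous PID rhythm tracker,
    adaptive antiresonance notch filtering, calibration of the contact
    pressure to a pulsatile pressure waveform, and a synthetic
    finger-hemodynamics simulator (pulsatile arterial pressure with
    respiratory and Mayer-wave rhythms, vasomotor tone, an S-shaped
    arctangent pressure-volume transfer and a slew-rate-limited
    actuator) so the full control stack can be initialized, stressed
    and evaluated at desk scale. Method-comparison statistics include
    repeated-measures Bland-Altman limits of agreement, delta-BP
    concordance, actuator-speed statistics and a power-budget
    calculator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
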