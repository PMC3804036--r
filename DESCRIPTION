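Package: pulsedepth
Title: Sensor-Displacement Based Pulse Depth Assessment for Tonometric
    Pulse Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assessment of pulse depth from applanation tonometry
    recordings of the radial artery. Implements the sensor-displacement
    based pulse depth index (PDI) together with the two contact-pressure
    based indices (optimal contact pressure with its normalised
    coefficient, and the pulse-amplitude-difference coefficient), a
    complete signal-processing pipeline (band-pass filtering, baseline
    removal, intersecting-tangent beat onset detection, amplitude
    envelope construction, automated skin-contact detection), a
    characterisation of the nonlinear contact-pressure versus
    displacement relation (quadratic and power-law fits), cohort-level
    repeatability and comparison statistics (coefficient of variation,
    one-way ANOVA, Duncan's multiple range test), and a fully seeded
    synthetic tonometry simulator that provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
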