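Package: aquagrf
Title: Estimating Vertical Ground Reaction Force from Wearable
    Accelerometry During Water-Based Jumping Exercise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for developing and validating regression equations that
    predict the vertical ground reaction force of countermovement jumps
    performed in water from body-worn accelerometer signals.  Includes a
    synthetic session generator (force-plate and triaxial accelerometer
    waveforms at three wear positions, heart rate at 1 Hz), zero-phase
    Butterworth filtering and landing-contact segmentation, Karvonen
    heart-rate-reserve intensity targets adjusted for immersion, backward
    stepwise elimination on ordinary least squares fits, and an agreement
    battery (Lin's concordance correlation coefficient, Bland-Altman limits
    of agreement, paired t, Pearson correlation, one-way repeated-measures
    ANOVA).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    data.table,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
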