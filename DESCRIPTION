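Package: callspace
Title: Spatiotemporal Communication-Space Analysis of Frog Calls Under Road Noise
Version: 0.1.0
Authors@R:
    person("Acoustic", "Ecology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how traffic noise constrains the acoustic
    communication of chorusing frogs. Converts field recordings to calibrated
    sound-pressure levels (dB re 20 uPa), measures per-call features (band-limited
    RMS source level at 1 m, spectral centroid frequency, duration, call rate),
    profiles ambient road noise per site-night, and evaluates a hemispherical
    active-space model: the masking radius at which a call's received level falls
    to the background-noise floor under spherical spreading plus linear excess
    attenuation, the communication volume (2/3)*pi*r^3, and the per-minute
    time-volume d * rate * (2/3)*pi*r^3. Includes a synthetic-soundscape
    generator with known ground truth, linear mixed-model inference with date
    nested in site, and acoustic-barrier insertion-loss scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
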