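Package: imugait
Title: Running Gait Analysis from a Single Sacral Accelerometer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates peak vertical ground reaction force, contact time, and
    flight time in running from the vertical acceleration recorded by a single
    sacrum-mounted inertial measurement unit. Implements truncated Fourier-series
    low-pass filtering, gravity-based sensor reorientation, acceleration-to-force
    conversion, and 20 N threshold detection of foot-strike and toe-off events,
    alongside the force-plate gold-standard pipeline and the full
    method-comparison toolkit (Bland-Altman bias and limits of agreement,
    smallest real difference, absolute and relative RMSE, proportional bias,
    Cohen's d). Ships a seeded spring-mass treadmill-running simulator that
    emits paired, unsynchronized force-plate and accelerometer traces with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
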