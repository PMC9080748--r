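Package: sidewindr
Title: Kinematics, Scaling and Path Analysis of Sidewinding Locomotion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for extracting sidewinding kinematics from digitized 3-D
    marker trajectories and relating them to morphology. Includes a synthetic
    trajectory and morphometrics generator with known ground truth,
    Savitzky-Golay smoothing with finite-difference kinematics, waveform
    geometry extraction (frequency, wavelength, peak-to-peak amplitude, skew
    angle, height lifted), allometric scaling statistics (AICc-ranked ANCOVA
    model search, reduced major axis regression with isometry tests), and
    observed-variable path analysis by maximum likelihood on covariance
    matrices with chi-square, RMSEA and AICc model comparison.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
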