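Package: planesweep
Title: Mirror-Swept Plane-Wave 3-D Ultrasound Simulation and Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and reconstruction toolkit for 3-D ultrasound imaging in
    which ultrafast plane waves are steered elevationally by a resonant tilting
    acoustic mirror. Schedules plane-wave transmissions against a sinusoidally
    tilting reflector, derives volume rates and planes-per-volume under the two
    sampling regimes, simulates pulse-echo channel data from synthetic wire and
    speckle phantoms, beamforms by delay-and-sum with optional coherent
    compounding, scan-converts the wedge of imaging planes into Cartesian 3-D
    volumes, recovers mirror kinematics from synthetic calibration sweeps, and
    quantifies image quality (FWHM resolution, contrast, contrast-to-noise
    ratio). A mechanical-translation scanning mode is included as a benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    signal,
    RNifti,
    tiff,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
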