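Package: renalimp
Title: Patient-Specific Forward Modelling of Renal Bio-Impedance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Voxelized quasi-static conduction modelling of the perirenal
    space for tetrapolar (four-electrode) bio-impedance measurement over the
    kidney. Builds a layered elliptic-cylinder trunk with a two-layer kidney
    ellipsoid and perirenal fat capsule, maps renal blood filling to layer
    resistivity through a parallel-conductor model, solves the conduction
    equation with a matrix-free finite-volume conjugate-gradient solver, and
    predicts static and pulsatile transfer impedance as a function of
    electrode spacing and kidney depth. Includes Doppler-derived renal
    blood-volume integration and its correlation against the simulated
    impedance waveform, plus synthetic waveform generators for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
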