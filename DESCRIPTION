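Package: retinastats
Title: Natural Image Statistics Across the Visual Field of a Spherical Model Retina
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates active visual exploration of procedurally generated
    three-dimensional scenes by walking avatars with thin-lens eye models
    (human and cat), renders image patches across a wide visual field through
    off-axis pinhole frustums, projects them onto an idealized spherical
    retina via tangent-plane homographies, and quantifies second-order
    (radially windowed power spectra, oriented elliptical power-law fits) and
    higher-order (orientation-tensor edge histograms, von Mises mixture fits,
    circular statistics) image statistics as a function of eccentricity and
    polar angle under different gaze strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
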