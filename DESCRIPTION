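Package: hydropore
Title: Hydration-Based Functional Annotation of Ion Channel Pores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating the conductive state of ion channel
    structures from the behaviour of water in the pore. Computes
    probe-sphere (HOLE-style) pore radius profiles by simulated-annealing
    Monte Carlo, bins water-oxygen trajectories into bulk-normalized axial
    density maps, Boltzmann-inverts the time-averaged density into a
    free-energy profile with a bulk-zero convention, classifies pores as
    wetted or de-wetted (open or closed), and reconstructs 1-D potentials
    of mean force from harmonic umbrella-sampling windows via the weighted
    histogram analysis method with Bayesian-bootstrap error bands. Includes
    synthetic generators for pseudo-atom pore walls, water trajectories
    drawn from a prescribed axial free-energy profile, and umbrella-window
    samples from a known potential, used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
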