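Package: crowddiff
Title: Lattice and Hard-Disk Monte Carlo Simulation of Receptor Diffusion
    in Crowded Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulation of the lateral diffusion of AMPA-type
    glutamate receptors in the crowded postsynaptic membrane. Receptors are
    modelled as tracers hopping on a periodic square lattice populated by
    completely-reflecting transmembrane obstacles and partially-reflecting,
    binding scaffold obstacles; steric exclusion among the tracers themselves
    (self-crowding) is resolved with a recursive two-pass hopping scheme that
    removes false self-blocking artifacts of sequential updating. A
    continuous-space Brownian dynamics engine for hard disks provides an
    independent reference for the lattice algorithm. Analysis tools compute
    ensemble-averaged mean squared displacement, the anomalous exponent of
    subdiffusion, and apparent, instantaneous and effective diffusion
    coefficients, and convert molecular footprints and areal densities into
    membrane area fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
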