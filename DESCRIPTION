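Package: scaffdeg
Title: Strain-Modulated Degradation Simulation for Bioresorbable
    Vascular Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the in-vivo degradation of poly-l-lactide acid
    (PLLA) bioresorbable vascular scaffolds driven by the maximum
    principal strain field frozen after deployment. A scalar degradation
    degree evolves per element as a power law in strain and time, the
    material fracture strain decreases linearly with the degradation
    degree, and elements whose fracture strain falls to their local
    strain are removed (element death). The package reports mass-loss
    trajectories, mass-weighted strain histograms, strut-discontinuity
    events, per-element fracture times and a scaffold-capacity
    surrogate, couples capacity to a reduced-polynomial hyperelastic
    artery response, fits the five kinetic coefficients to
    degradation-experiment records by bounded nonlinear least squares,
    and generates synthetic stent-like strain fields and degradation
    datasets for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
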