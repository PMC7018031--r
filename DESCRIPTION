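Package: motortraffic
Title: Simulation and Correlation-Imaging Analysis of Molecular Motor
    Traffic on Microtubules
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying crowding of processive molecular motors
    (kinesins) on microtubules. Provides an exact continuous-time kinetic
    Monte Carlo simulator of the multi-lane totally asymmetric simple
    exclusion process with Langmuir kinetics (TASEP-LK), extended with an
    elevated detachment rate for motors whose forward step is blocked; a
    synthetic TIRF image-stack generator with a Gaussian point-spread
    function, Poisson shot noise and camera digitization; correlation
    imaging analyses (FCS-based motor density, spatiotemporal correlation
    velocity and run-length extraction); a single-particle tracking
    pipeline (2-D Gaussian spot detection, nearest-neighbour linking,
    mean-displacement velocity, cumulative run-length fits); and the
    staged fitting procedure that recovers kinetic parameters from
    concentration-series observables by low-density linear fits followed
    by a grid search over lane number, interaction range and the
    constrained-motor detachment ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
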