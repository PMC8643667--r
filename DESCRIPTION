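Package: telodyn
Title: Single-Molecule FRET Analysis of Telomere Overhang Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule FRET (smFRET)
    intensity time traces of shelterin-bound telomeric overhangs. Provides a
    continuous-time Markov chain trajectory simulator with a camera-level
    emission model (shot noise, donor leakage, photobleaching, flow-injection
    binding, PIFE), donor-leakage correction and ALEX-based donor-only
    exclusion, ensemble FRET histograms with Gaussian mixture fits, heatmaps,
    steady/dynamic trace classification, Gaussian-emission hidden Markov model
    fitting with transition density plots and discrete-level counting, and
    dwell-time and equilibrium binding kinetics (exponential MLE with
    truncation correction, Langmuir K_D estimation, PIFE step detection).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
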