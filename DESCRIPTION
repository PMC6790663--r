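Package: dffit
Title: Force-Field Parametrization by Distribution-Function Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits pair-potential parameters of simple molecular fluids so
    that radial and energy distribution functions (RDF/EDF) computed from
    candidate parameters reproduce target distribution functions. Targets
    carry per-bin block-averaged uncertainties; the objective is an
    uncertainty-weighted residual sum of squares minimized with the
    covariance matrix adaptation evolution strategy (CMA-ES), with an
    adaptive sampling-budget doubling rule and replicate-derived convergence
    thresholds. Includes a Metropolis Monte Carlo sampler of periodic
    Lennard-Jones and rigid three-site water-like fluids, energy-histogram
    bin-definition systems, extended-XYZ trajectory I/O and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
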