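Package: eamrec
Title: Parameter Recovery and Identifiability Simulations for
    Evidence-Accumulation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation toolkit for studying parameter identifiability in
    the two dominant evidence-accumulation models of two-alternative forced
    choice data: the diffusion decision model (DDM) and the linear ballistic
    accumulator (LBA). Provides first-passage-time densities, likelihoods
    and trial simulators for both models, sampling of data-generating
    parameter vectors from empirically calibrated truncated multivariate
    normal distributions, generation of choice-RT datasets targeted at
    specific error rates under stimulus, difficulty and speed-accuracy
    designs, Bayesian estimation by differential-evolution MCMC with
    convergence monitoring (R-hat, effective sample size), and recovery
    statistics (Pearson correlations, RMSD, absolute-deviation intervals,
    posterior pairwise and partial correlations, parameter-ratio recovery).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
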