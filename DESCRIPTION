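Package: flimmixer
Title: MLP-Mixer Regression of Fluorescence Lifetimes from TCSPC Decays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for fluorescence lifetime
    imaging (FLIM) based on time-correlated single-photon counting (TCSPC).
    Simulates multiexponential decay histograms with a Gaussian instrument
    response function and Poisson photon noise, trains a compact MLP-Mixer
    neural network to regress amplitude-weighted average lifetimes directly
    from normalized histograms, and benchmarks it against classical
    estimators (nonlinear least squares, variable projection, and the
    center-of-mass method) on synthetic sweeps and per-pixel FLIM image
    stacks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    minpack.lm,
    pracma,
    tiff,
    png,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
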