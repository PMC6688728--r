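Package: dfcsim
Title: Ground-Truth Simulation and Evaluation of Sliding-Window Dynamic
    Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates coupled neural signals with known time-varying
    connectivity and evaluates how well conventional sliding-window
    connectivity metrics recover it. Ground-truth coupling switches between
    hidden states with Gamma-distributed lifetimes and drives either a
    two-node order-2 multivariate autoregressive model built from
    eigen-parameters of its companion form, or Jansen-Rit neural-mass
    models (two coupled nodes, or a delayed cortical network whose
    structural connectivity tensor activates one resting-state subnetwork
    at a time). Connectivity is estimated over 50%-overlapping sliding
    windows with five metrics (amplitude envelope correlation, coherence,
    imaginary coherence, phase locking value, phase lag index), optionally
    after inverse-distance linear mixing and symmetric multivariate
    orthogonalization. The evaluation harness provides distribution summary
    statistics (including excursions from the median), static-versus-dynamic
    Mann-Whitney tests, spline-interpolated error and correlation against
    ground truth, Friedman tests of the window-length effect, signal-to-noise
    sweeps, within- versus outside-network contrasts, and orthogonally
    constrained non-negative tensor factorization for network recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
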