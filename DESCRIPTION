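Package: blockstate
Title: Kinetic Modeling of Calcium-Dependent Open-Channel Block of NMDA
    Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating and fitting a two-plane Markov kinetic
    model of NMDA receptor gating, trapping open-channel block by
    memantine, and calcium-dependent desensitization.  Includes
    concentration-jump protocol simulation (agonist steps,
    concentration-inhibition series, recovery-from-desensitization
    trains), a staged multistart derivative-free fitting pipeline with
    lognormal-jittered starts and t-based across-trial intervals,
    thermodynamic analysis of desensitized-state stabilization, Hill-type
    dose-response fitters (concentration-inhibition, intracellular-calcium
    dependence, recovery exponentials with weighted time constants, and
    neuroprotection curves), ligand-optimization-method calibration of
    calcium-selective electrodes and calcium buffers, and synthetic
    whole-cell-like data generators for end-to-end parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
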