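Package: sbmlsens
Title: Perturbation Ensembles, Steady-State Interventions and Sensitivity
    Analysis for SBML Models
Version: 0.1.0
Authors@R: person("York", "Modelling", email = "modelling@example.org",
    role = c("aut", "cre"))
Description: Generates ensembles of perturbed SBML models using local
    one-at-a-time sweeps, latin-hypercube sampling and eFAST sinusoidal
    search curves; snapshots a solved model's state into a new SBML file;
    injects interventions (set or scale a parameter or species
    concentration) at steady state; and analyses solver responses with
    partial rank correlation coefficients and eFAST variance
    decomposition. Ships a deterministic adaptive ODE integrator for the
    supported SBML subset and a Th17/Th1 phenotype-switching case study
    exercising the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    graphics,
    compiler
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
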