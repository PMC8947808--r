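Package: fluxnlp
Title: Steady-State and Isotopically Nonstationary 13C Metabolic Flux
    Analysis by Constrained Nonlinear Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates intracellular metabolic fluxes and metabolite pool
    sizes from stable-isotope labeling measurements. Carbon atom transitions
    of a metabolic network are translated into cumomer or elementary
    metabolite unit (EMU) balances; for isotopically nonstationary
    experiments the labeling dynamics are transcribed into algebraic
    constraints with Radau IIA orthogonal collocation, and fluxes, pool
    sizes and measurement scaling factors are estimated by minimizing a
    variance-weighted sum of squared residuals subject to the model
    equations as equality constraints. Supports single and tandem mass
    spectrometry measurements, natural-abundance correction, multistart
    estimation with high-order refinement, chi-square goodness-of-fit
    assessment, parametric bootstrap confidence intervals, and export of
    networks and flux maps to Escher-readable JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    minpack.lm,
    deSolve,
    boot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'parse.R'
    'network.R'
    'states.R'
    'arrays.R'
    'input.R'
    'nabund.R'
    'measurement.R'
    'forward.R'
    'oracle.R'
    'collocation.R'
    'nlp.R'
    'solve.R'
    'multistart.R'
    'bootstrap.R'
    'toy.R'
    'escher.R'
    'cli.R'
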