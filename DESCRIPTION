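Package: invivomca
Title: In Vivo Metabolic Control Analysis from Thermodynamic Flux Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating rate-limiting enzymes in small metabolic
    networks from steady-state perturbation data. Implements thermodynamic
    flux analysis (TFA) on a reduced stoichiometric model with measured
    extracellular rates and intracellular metabolite concentrations as
    constraints, Monte-Carlo sampling of reaction Gibbs energies with
    quartile-based equilibrium classification, dual-regime elasticity
    estimation (thermokinetic affinity near equilibrium, lin-log regression
    far from it), and flux/concentration control coefficients by the matrix
    method with Monte-Carlo uncertainty propagation. Ships a reduced
    central-carbon plus L-cysteine model of Escherichia coli and a kinetic
    toy-model generator that emulates feeding-step perturbation experiments
    and provides a finite-difference control-coefficient oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    xml2
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with scipy (>= 1.9) on the PATH for the
    HiGHS-based linear/mixed-integer solver backend
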