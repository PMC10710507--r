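Package: relaxkin
Title: Kinetic Discrimination of Induced-Fit and Conformational-Selection
    Ligand Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing receptor-ligand binding kinetics measured by
    stopped-flow fluorescence and 19F saturation-transfer NMR. Implements
    closed-form near-equilibrium relaxation rates for three-state induced-fit
    and conformational-selection binding schemes, a mass-action simulator and
    eigenvalue oracle, seeded differential-evolution fitting of single- and
    double-exponential time traces with AIC model selection, error-weighted
    joint fitting of the two relaxation rates across a ligand concentration
    series with a fixed overall dissociation constant, and Bloch-McConnell
    saturation-transfer fitting of two-state conformational exchange rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
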