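Package: n2otrace
Title: Closed-Vial 15N-N2O Tracer Simulation and Analysis for Diazotrophic
    Nitrous Oxide Fixation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for batch-incubation 15N2O tracer experiments on
    nitrogen-fixing cyanobacteria: bookkeeping of sealed-vial headspace gas
    composition and spikes, Henry's-law gas-liquid partitioning of N2O,
    15N isotope-pool accounting (atom percent excess, pool mixing,
    isotopologue splits), a forward ODE simulator of the closed-vial
    incubation (two-step N2O -> N2 -> biomass transfer, competitive
    nitrogenase kinetics, growth, O2 accumulation, instrument noise), and
    the downstream analysis pipeline (linear consumption-rate estimation,
    acetylene-reduction conversion, run comparisons, nitrogen budget
    closure, one-way ANOVA with Tukey letters). Includes packaged
    incubation scenarios, long-format CSV / YAML / JSON input-output, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
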