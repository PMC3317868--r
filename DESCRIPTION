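Package: fbatools
Title: Constraint-Based Metabolic Model Editing, Flux Analysis and Pathway Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale toolkit for constraint-based analysis of
    stoichiometric metabolic models. Reads and writes SBML in three dialects
    (Level 2 with COBRA-style notes, Level 3 with the Flux Balance
    Constraints package, and bare stoichiometry-only documents, which are
    auto-constrained on import), supports interactive and batch model
    editing, and runs flux balance analysis, flux variability analysis and
    flux-sum minimization on a built-in bounded-variable simplex solver that
    reports shadow prices and reduced costs. Includes structural diagnostics
    (dead-end metabolites, synonymous reactions), boolean gene-protein-
    reaction knockout simulation, metabolite producibility checks,
    tab-separated result export, interactive SVG pathway maps with flux
    overlays and KEGG hyperlinks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
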