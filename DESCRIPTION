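Package: vitisflux
Title: Constraint-Based Flux Analysis of Grapevine Cell Suspension Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stoichiometric modelling of heterotrophic plant cell metabolism
    with quadratic flux minimization, built around a curated reconstruction of
    central carbon, nitrogen and polyphenol metabolism in the GT3 Vitis
    vinifera (Gamay Teinturier) cell line. Converts measured biomass time
    courses, accumulated-metabolite contents, enzyme capacities and
    respiration rates into bound and coupling constraints on a steady-state
    flux balance problem, solves the strictly convex flux-minimization
    program, audits cofactor (ATP/NADH/NADPH) and 2-oxoglutarate budgets, and
    compares flux maps across nitrogen-supply conditions. Includes SBML and
    reaction-table input/output, a synthetic-data generator for end-to-end
    validation against a known ground-truth flux vector, and a command-line
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    quadprog,
    xml2,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
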