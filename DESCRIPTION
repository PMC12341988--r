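Package: redoxflux
Title: Constraint-Based Analysis of Redox Trade-Offs in Methanotroph Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based modelling of methanotrophic, autotrophic
    and heterotrophic growth in verrucomicrobial methanotrophs. Provides a
    metabolic model container with SBML (Level 3, fbc) and JSON readers and
    writers, flux balance analysis with linear flux-split (ratio) constraints
    and parsimonious flux reporting, flux variability analysis, model-hygiene
    checks (elemental balance, Gibbs-based directionality, energy-generating
    cycle detection, biomass normalization, maintenance fitting), condition
    scans and phase planes for electron-transport-chain trade-offs, uniform
    flux sampling of the steady-state polytope, differential-flux statistics
    (Kolmogorov-Smirnov distance and log2 fold change of medians), and mass
    flow graphs with PageRank reaction centrality. A deterministic generator
    for a small methanotroph-style model makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
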