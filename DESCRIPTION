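Package: crowdflux
Title: Crowding-Constrained Metabolic Flux Polytopes and Two-Cell Lactate Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based modeling of overflow metabolism under a
    macromolecular crowding constraint. Provides the exactly solvable
    coarse-grained model of a single cell and of a donor/acceptor cell pair
    coupled by a lactate shuttle, together with a general toolkit for
    large-scale stoichiometric networks: tabular and SBML input, two-cell
    replication with shared-nutrient coupling constraints, reduction of the
    steady-state flux space to an independent-variable polytope by
    Gauss-Jordan elimination, ellipsoid-rounded Hit-and-Run sampling with a
    Boltzmann bias interpolating between uniform exploration and linear-
    objective maximization, and downstream analyses (ATP yield curves,
    pathway fractions, glucose and beta scans, Pearson flux correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    boot,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
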