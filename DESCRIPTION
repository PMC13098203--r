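Package: strainforge
Title: High-Throughput Generation, Curation and Comparison of Strain-Specific
    Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and comparing cohorts of strain-specific
    genome-scale metabolic models (GEMs). Provides an S4 data model for
    compartmentalized stoichiometric networks with SBML Level 3 (FBC v2)
    input/output, mass- and charge-balance auditing with R/X pseudo-element
    support, duplicate detection and merging for universal reaction-database
    models, post-carve refinement of draft strain models (gap-fill pruning,
    restoration of gene-evidenced disconnected reactions, biomass
    installation), pan-model construction with energy-generating-cycle
    detection, a constraint-based simulation suite (FBA and parsimonious FBA
    on GLPK, fermentation profiling, pyruvate-formate-lyase scans, ATP-yield
    maximization, leave-one-out nutrient essentiality, casein-peptide milk
    growth, cross-feeding screens), reaction presence/absence comparison with
    hierarchical clustering, and a deterministic toy-universe generator used
    as the desk-scale test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    xml2,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
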