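Package: ilscreen
Title: COSMO-RS-Style Screening of Ionic Liquids for Liquid Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for conductor-like screening model (COSMO-RS) style
    solvent screening of ionic liquids. Reads TURBOMOLE-style COSMO segment
    files and two-column sigma-profile tables, builds and mixes sigma
    profiles, solves the self-consistent sigma-potential equation for a
    solvent ensemble, computes infinite-dilution activity coefficients and
    extraction capacities of a solute in every cation-anion combination of a
    screening manifest, and ranks the ionic liquids by capacity. Includes a
    seeded synthetic-data generator for sigma surfaces and profiles so the
    whole pipeline is testable without quantum-chemistry output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
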