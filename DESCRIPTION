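Package: lampart
Title: Torsional-Group-Partitioned Local Approximate Models of
    Intramolecular Energy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates Local Approximate Models (LAMs) of a
    flexible molecule's intramolecular energy, dependent conformational
    degrees of freedom and atomic point charges as functions of its
    flexible torsion angles, for use in crystal structure prediction.
    Supports partitioning of the torsions into additive torsional groups,
    uniform reference grids in bounded and wraparound dialects, adaptive
    grid refinement within the crystallographically relevant energy
    region, nearest-reference Taylor evaluation with the group-additivity
    combination rule, oracle-call accounting, database serialization, and
    an accuracy-assessment harness. A built-in synthetic conformational
    model with closed-form constrained minima and analytic derivatives
    stands in for isolated-molecule quantum-mechanical minimizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
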