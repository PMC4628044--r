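Package: triqsar
Title: QSAR Modeling of 1,2,3-Triazole Cytotoxicity with Graph and Geometry Descriptors
Version: 0.1.0
Authors@R: person("QSAR", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative structure-activity relationship
    (QSAR) analysis of disubstituted 1,2,3-triazole cytotoxicity against four
    cancer cell lines (HuCCA-1, HepG2, A549, MOLT-3). Computes the seven
    molecular descriptors used by the published per-cell-line models (GETAWAY
    R-indices R5e+ and R7m, Moran autocorrelations MATS7m and MATS8v, the
    radial distribution function RDF105m, the lopping centric index, and the
    aromatic ester count nArCOOR) from 3D structures; converts and classifies
    IC50 activity data; performs correlation filtering, stepwise multiple
    linear regression and leave-one-out cross-validation; applies the four
    published equations to score and rank candidate analogs; and ships
    reference tables plus a synthetic-data generator so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
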