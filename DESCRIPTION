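Package: rna2d
Title: Template-Based Prediction and Visualisation of RNA Secondary Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Draws RNA secondary (2D) structure diagrams in standardised,
    community-recognisable layouts by matching a query sequence against a
    library of curated 2D templates. Each template carries a reference
    sequence, a dot-bracket structure and fixed per-nucleotide coordinates.
    The pipeline selects the best-matching template with a local affine-gap
    alignment score, transfers the template base pairs onto the query via a
    global alignment, inherits the template coordinates, places insertions by
    loop geometry, minimises residual overlaps by exhaustive 30-degree
    hairpin rotations, and emits coloured SVG diagrams together with
    dot-bracket and per-nucleotide classification files. A synthetic template
    and query generator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
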