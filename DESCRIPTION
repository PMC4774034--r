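Package: scpath
Title: Spatial Care Path Analysis of Health Care Access and Point-of-Care
    Technology Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models health care access as a two-stage spatial care path: the
    fastest road route from a populated place to its closest diagnostic
    facility, then onward to a single tertiary care destination. Builds a
    routable travel-time network from raw road polylines (snap integration,
    connector edges for off-network points), computes population-weighted
    access summaries and 15-minute travel-time histograms, and optimizes
    point-of-care technology placement with a constrained P-median model
    (exact enumeration and a Teitz-Bart style swap heuristic) under
    widespread and limited-resource deployment scenarios. Includes a
    synthetic region generator so every stage runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
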