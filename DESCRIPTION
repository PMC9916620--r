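Package: agcorridors
Title: Least-Cost Corridor Modelling for Pollinators in Agricultural
    Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models landscape connectivity for pollinating insects across
    intensively farmed landscapes. Pesticide-use records are converted to
    per-acre toxic loads (honey-bee contact LD50 equivalents), toxic loads
    to integer resistance-to-movement surfaces anchored to the urban to
    natural genetic-differentiation ratio, and resistance surfaces to
    least-cost corridors via Dijkstra cost-distance with backlink tracing.
    A factorial experiment crosses three agricultural-margin treatments
    (restored, current, eliminated) with three resistance levels and
    summarises corridors with connectivity statistics: total and unique
    path length, mean distance to the nearest path, path convergence,
    commonality across resistance levels, and land-cover composition.
    A seeded synthetic-landscape generator emulates the structure of an
    agricultural valley (rectangular crop parcels ringed by linear margins,
    urban patches, water, and a low-resistance natural perimeter) so the
    whole pipeline runs and is testable without external GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
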