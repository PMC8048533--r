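Package: lastmile
Title: Route Optimization for Last-Mile Vaccine and Medical Supply Distribution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Plans delivery routes for district-level distribution of vaccines
    and other medical supplies from a depot to a set of health centers, using
    a heterogeneous fleet with separate cold (refrigerated) and dry cargo
    compartments, asymmetric road distances, categorical road and vehicle
    condition penalties, and a maximum route duration. The routing problem is
    solved either as an exact mixed-integer program (through an external
    branch-and-cut backend) or by a fast two-stage index-rule construction
    heuristic embedded in an elite-set branch-and-bound with minimum
    spanning tree lower bounds. Includes readers and writers for a
    seven-table plain-text instance format, demand scaling against available
    supply, cold/dry product grouping, post-hoc fuel and per-diem costing,
    and a seeded generator of district-like synthetic instances.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with scipy (>= 1.9) on the PATH, used by
    the mixed-integer programming backend.
Config/testthat/edition: 3
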