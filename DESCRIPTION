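Package: tirewash
Title: Daily Fate and Transport of Tire-Derived 6PPD-Quinone in Urban Watersheds
Version: 0.1.0
Authors@R: person("Longfellow", "Labs", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, process-based simulator for the tire-derived
    contaminant 6PPD-quinone (6PPD-Q) in small gridded urban watersheds with
    explicit storm-sewer infrastructure. Computes traffic-scaled daily road
    deposition, first-flush wash-off, D8 surface and pipe routing, linear
    (Koc) sorption within a four-layer soil column, environmentally modulated
    first-order decay, and pour-point concentration series, with a closed
    daily mass balance. Includes a seeded synthetic-watershed generator so
    every component is testable without external GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
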