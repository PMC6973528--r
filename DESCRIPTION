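Package: triplelink
Title: Typed Triple Graphs for Linking Clinical and Environmental Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-memory RDF-style triple graph with declarative
    table-to-graph (uplift) mappings, temporo-spatial enrichment
    (great-circle nearest weather station, region containment, exposure
    windows, weekly surveillance alignment), PROV-style provenance
    recording, and projection of the enriched graph back to a per-patient
    analytic table (downlift). Includes a seeded synthetic-data generator
    emulating daily station observations, weekly regional infection
    counts, gridded climate fields and boundary polygons, so the whole
    linkage pipeline can be exercised and verified offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    optparse,
    geosphere,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
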