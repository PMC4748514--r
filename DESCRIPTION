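Package: exergraph
Title: Exergame Telemetry as Linked Open Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds, validates, serializes, queries and simulates exergame
    game-session telemetry as RDF, following an OWL ontology for exergames
    in which per-iteration game metrics (success, reaction time, goal time)
    are attached to sessions through n-ary metric-relation nodes and ordered
    with rdf:Seq containers. Includes readers and writers for Turtle,
    RDF/XML and N-Triples with deterministic blank-node canonicalization, a
    SPARQL basic-graph-pattern query engine with a brute-force oracle, a
    structural validator with an anonymization check, an R2RML-inspired
    CSV-to-RDF converter, and a seeded synthetic-pilot generator emulating a
    living-lab deployment of elderly players.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
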