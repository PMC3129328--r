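Package: ontoquery
Title: Uniform Query Interface for Heterogeneous Ontology Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A single service contract for querying biomedical ontologies
    regardless of where they live: local OBO 1.2/1.4 flat files, local OWL
    (RDF/XML) documents, or remote servers speaking this package's own
    REST/JSON dialect. The contract covers ontology listing, term lookup,
    keyword search, synonym and definition retrieval, and hierarchy
    traversal (parents, children, ancestors, descendants, path to root).
    Composable decorators add a two-layer cache with stale-fallback when a
    backend dies, federated multi-source search, priority-ranked result
    subsetting, and regular-expression translation of term accessions
    between identifier namespaces. Includes a deterministic synthetic
    ontology generator, a loopback HTTP server, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    xml2,
    httpuv,
    curl,
    callr,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
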