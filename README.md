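# ontoquery

Uniform programmatic access to biomedical ontologies, wherever they
live: local OBO 1.2/1.4 flat files, local OWL (RDF/XML) documents, or a
remote server speaking this package's REST/JSON dialect.

Anyone annotating life-science data with ontology terms faces the same
friction: every source has its own identifier scheme, feature set and
access idiom, and the same ontology can differ between repositories in
accession style, version and even term count. `ontoquery` is for
bioinformaticians who want one small, stable API over all of that —
for annotation pipelines, curation tooling, and interactive term
lookup — without caring where a given ontology happens to be served
from.

## The model

The unit of exchange is the **ontology term**, a tuple of

- *term accession* (e.g. `GO:0043227`),
- *term label* (carried for convenience; never part of identity),
- *ontology accession* (e.g. `GO`),

with identity given by the pair (ontology accession, term accession) —
a term accession alone is not globally unique.

A single behavioural contract of 16 operations covers ontology
listing/records, keyword search (exact or substring, optionally over
annotation properties, optionally including obsolete terms), term
lookup, synonyms/definitions/annotations, and hierarchy traversal
(roots, parents, children, ancestors, descendants, path to root). Only
`is_a` edges define the hierarchy; other typed relations are exposed
through `get_relations()`. Traversals are iterative and cycle-safe.

Two backends implement the contract:

- `file_service()` — parses OBO and OWL files into in-memory graphs,
- `http_backend()` — a client for servers started with `serve()`,

and four composable decorators wrap any implementation while
preserving it:

| decorator | behaviour added |
|---|---|
| `cached()` | TTL cache (24 h default) plus an eternal layer that answers when the backend is down |
| `composite()` | federated fan-out over several services, results concatenated in service order |
| `sorted_subset()` | search results filtered to a priority list of ontologies and ranked by it |
| `translated()` | regex rewriting of accessions between namespaces (e.g. `NCBITaxon_1` ↔ `NCBITaxon:1`) |

## Worked example

```r
library(ontoquery)

svc <- file_service(list(toy_graph()))   # or file_service("myontology.obo")

hits <- search_all(svc, "cell", search_options(include_properties = TRUE))
terms_as_data_frame(hits)
#>     accession      label ontology_accession obsolete
#> 1 TOY:0000002       cell                TOY    FALSE
#> 2 TOY:0000003     neuron                TOY    FALSE
#> 3 TOY:0000004 glial cell                TOY    FALSE
```

Three hits: `cell` by label equality, `glial cell` by label substring,
and `neuron` because its *definition* contains "cell" and property
search was requested.

```r
neuron <- get_term(svc, "TOY:0000003", "TOY")
get_definitions(svc, neuron)
#> [1] "An electrically excitable cell."

terms_as_data_frame(get_term_path(svc, neuron))
#>     accession             label ontology_accession obsolete
#> 1 TOY:0000001 anatomical entity                TOY    FALSE
#> 2 TOY:0000002              cell                TOY    FALSE
#> 3 TOY:0000003            neuron                TOY    FALSE
```

The path runs root-first down to the query term. Synonyms are
returned stripped of scope and cross-references, for uniformity across
backends; the raw scoped form stays available:

```r
glia <- get_term(svc, "TOY:0000004", "TOY")
get_synonyms(svc, glia)
#> [1] "neuroglia"
get_annotations(svc, glia)
#> $synonym
#> [1] "\"neuroglia\" BROAD [FMA:0]"
```

Serving the same ontology over HTTP and querying it remotely is two
lines, and the remote service honours the identical contract:

```r
server <- serve_background("toy.obo")
remote <- cached(http_backend(server$base_url))
search_all(remote, "cell")          # same answers as the local service
```

A command-line entry point wraps the same operations
(`inst/cli/ontoquery.R`):

```sh
Rscript inst/cli/ontoquery.R search cell --exact --input toy.obo
Rscript inst/cli/ontoquery.R path TOY TOY:0000006 --input toy.obo --format tsv
```

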