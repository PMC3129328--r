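---
title: "Uniform ontology access: model, design choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uniform ontology access: model, design choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoquery)
```

## The problem and the model

Biomedical ontologies are served from heterogeneous places — local OBO
flat files, local OWL documents, remote repositories — and each source
has its own identifiers, feature set and access idiom. Even a single
ontology can differ between repositories in accession scheme, version
and term count, so code written against one source does not transfer to
another. `ontoquery` puts one behavioural contract in front of all of
them.

The unit of exchange is the *ontology term*, modelled as a tuple of
(1) term accession, (2) term label, and (3) the accession of the owning
ontology. The identity key is the pair (ontology accession, term
accession): a term accession alone is not globally unique — some
repositories use labels as accessions — and the label is carried for
convenience only. Replicas of an ontology in two sources are treated as
different ontologies (their ontology accessions differ), never merged.

Sixteen operations make up the contract: ontology listing and record
lookup; global and per-ontology keyword search; term lookup (with and
without naming the ontology); full term listing; raw annotations;
synonyms and definitions; and six hierarchy operations (roots, direct
parents/children, all ancestors/descendants, path to root). Two
backends implement it — `file_service()` over parsed files and
`http_backend()` over the package's REST dialect — and four decorators
wrap any implementation while preserving it.

## Hierarchy semantics

Only `is_a` (subclass) edges define the hierarchy. Other typed
relations (`part_of`, ...) are kept in the graph and exposed solely
through `get_relations()`, together with cross-references. No reasoning
is performed: asserted subclass axioms only, no inferred subsumption,
no equivalence merging, and restriction-based superclasses in OWL are
ignored.

Traversals are iterative (explicit work-list), never call-stack
recursive, and each node is visited at most once, so they terminate on
cyclic input. Cycles are tolerated in `ancestors()`/`descendants()` —
closure over a cycle is well-defined — but rejected in
`path_to_root()`, whose contract is a unique linear chain: revisiting
an accession on the chosen path raises a cyclic-hierarchy error naming
the repeated accession. At a multi-parent step the lexicographically
smallest parent accession is chosen; only this one canonical path is
returned, not all paths under multiple inheritance.

Everywhere an ordering is not semantically forced, output is sorted
lexicographically under C collation (`method = "radix"`), so results
are reproducible across machines and locales.

**Obsolete terms.** Obsolete terms keep their edges, remain retrievable
by accession, and appear (flagged) in full term listings, but are
excluded from root listings and — by default — from search. This mirrors
common repository behaviour; it is a documented package choice, since
sources disagree and no single convention is universal.

## File formats

**OBO.** The reader targets OBO 1.2 and accepts the 1.4 synonym syntax
plus the obsolete pre-1.2 scoped tags (`exact_synonym` etc.),
normalizing the latter. Trailing `! comment` text is stripped before
value parsing, except inside quoted strings; backslash escapes are
resolved after that. Synonyms keep their scope (`EXACT`, `BROAD`,
`NARROW`, `RELATED`; absent scope maps to `UNSPECIFIED`) and
cross-references at parse time; the service-level `get_synonyms()` and
`get_definitions()` strip scope and xrefs so output is uniform across
backends, while `get_annotations()` still exposes the raw scoped forms.
Logical tags (`intersection_of`, `union_of`, `disjoint_from`) and other
unknown tags are preserved verbatim as annotations, not interpreted —
consistent with the no-reasoning scope. The ontology accession defaults
to the header's `ontology` tag uppercased (repositories commonly use
the uppercased name abbreviation); an explicit override always wins.
The writer emits terms in accession order and round-trips exactly on
labels, edges, scoped synonyms, definitions, xrefs, typed relations and
obsolete flags.

**OWL (RDF/XML).** Every named class except `owl:Thing` becomes a term.
Labels are resolved in order of preference and availability: each
user-specified annotation property of the `label_policy()`, then
`rdfs:label`, then `skos:prefLabel`, then the fragment of the class URI
— so every class gets a non-empty label. Accessions derive from the URI:
the substring after the last `#`, else after the last `/`, else the URI
itself. When two class URIs in different namespaces share a fragment,
the first in document order wins and later ones are dropped with a
warning — a deterministic version of the discard-on-collision behaviour
an accession-keyed index forces. Synonym sources are `skos:altLabel`
and a pinned OBO-in-OWL property set (`hasExactSynonym`,
`hasBroadSynonym`, `hasNarrowSynonym`, `hasRelatedSynonym`, plus
`hasSynonym` for unscoped ones); definitions come from
`skos:definition` and `hasDefinition`; cross-references from
`hasDbXref`. A class is obsolete when `owl:deprecated` is true or when
it sits transitively under an `ObsoleteClass` bucket; bucket edges
never enter the hierarchy. The writer offers two dialects — SKOS and
OBO-in-OWL — so dialect-invariance is testable; synonym scopes survive
only the OBO-in-OWL dialect (SKOS has no scope vocabulary), which is
why cross-format equality is defined on a *normalized view*: labels,
synonym texts, definition texts, `is_a` edges, xrefs, obsolete flags.
Typed relations other than `is_a` are not represented in OWL output.
Terms with empty labels cannot round-trip through OWL (the fragment
fallback would replace the empty label), so the generator always
assigns labels.

## Search semantics

Ontology and term accessions are case-sensitive (they are identifiers);
queries are case-insensitive (they are human text). Exact search means
full-string equality, non-exact means substring containment, so the
exact result set is always contained in the non-exact one. With
`include_properties` the candidate strings are the label plus synonym
texts, definition texts and *all* other string annotation values — a
documented superset of repositories' "include properties" knobs. There
is no stemming, fuzzy matching or external indexing; the in-memory
graphs are scanned directly, which is adequate for ontologies in the
tens of thousands of terms.

## Decorators

`cached()` adds two layers. Every call first consults a TTL layer
(default expiry 24 hours); a miss goes to the wrapped service, and a
success is stored in both the TTL layer and an eternal layer. If the
wrapped service fails, the eternal layer answers if it can — so a warm
cache survives a backend outage — otherwise the failure propagates.
Only successful results are cached; contract-level errors (not-found,
cyclic) are answers about the data and are never treated as outages.
The time source is injectable, so expiry is testable without waiting a
day; the eternal layer is unbounded and in-memory, since cache storage
media are an orthogonal concern.

`composite()` federates an ordered list of services. Searches and
ontology listings fan out to every backend and concatenate in
service-declaration order — deterministic regardless of backend
scheduling. Single-valued lookups return the first non-absent answer in
service order, so replicas are never merged: results from the same
ontology in two sources differ enough that integrating them is
deliberately not attempted, and no deduplication is performed. A
failing backend is skipped with a warning (dropout redundancy) unless
`strict = TRUE`. The `workers` argument is accepted for interface
compatibility, but execution is sequential: R is single-threaded in
this setting, ordering is fixed by declaration order anyway, and a
sequential variant is the established choice for an R binding.

`sorted_subset()` truncates search results to a priority list of
ontologies and ranks them in list order, with a stable sort so ties
keep the inner service's order. Non-search operations pass through.

`translated()` bridges identifier namespaces — e.g. OWL-style
`NCBITaxon_1` versus OBO-style `NCBITaxon:1` — by testing incoming term
and ontology accessions against each mapping's match pattern in order
and applying the first match's rewrite rules before delegating.
Results are returned as the inner service produced them: the motivating
use case is making foreign accessions *resolvable*, which needs request
translation only, so reverse-translating responses is off by default.

Decorators compose in any order, and with neutral configuration (fresh
cache, full-coverage priority, empty mapping list, healthy backends)
each is observationally equal to the service it wraps — a property the
test suite checks wholesale.

## REST dialect

`serve()` exposes any service as GET routes returning UTF-8 JSON:
`/ontologies`, `/ontologies/{o}`, `/ontologies/{o}/roots`,
`/ontologies/{o}/terms`, `/ontologies/{o}/terms/{t}`, nine per-term
sub-routes, and `/search` with `query`/`exact`/`properties`/`obsolete`/
`ontologies` parameters. JSON is the only wire format: a second format
would double the test surface without adding behaviour. Term accessions
in paths are percent-encoded (`:` as `%3A`); `?accession=` is accepted
as a fallback. Unknown ontology or term maps to 404 with a JSON error
body, an empty query to 400, a cyclic hierarchy on the path route
to 422. List responses are capped at `max_results` (default 10000,
echoing repositories' large max-hit caps) with a `"truncated": true`
envelope. `http_backend()` implements the whole contract over this
dialect; connection failures surface as service-unavailable errors,
which `cached()` absorbs when warm. Because an in-process HTTP client
cannot be answered by an in-process single-threaded server,
`serve_background()` stands the server up in a child R process; the
loopback tests compare client and direct access operation by operation.

## The synthetic generator

`random_graph()` emulates the structural features the contract cares
about: a forest with configurable root count, soft fan-out cap,
multi-parent edges (default rate 0.1 — multiple inheritance is present
but minoritary in curated ontologies), scoped synonyms and referenced
definitions (defaults 0.3 — of the order seen in curated OBO
ontologies, where a minority-to-half of terms carry them), obsolete
terms (default 0.05, matching the few-percent obsolete fraction typical
of mature ontologies) and cross-references (default 0.2). Parents are
drawn only from already-created terms, so generated graphs are acyclic
by construction; cyclic inputs for termination tests are built by hand.
The generator runs under a private RNG stream keyed by its seed and
restores the caller's stream.

What it does *not* emulate: realistic label vocabulary (a fixed
40-word list), realistic depth/breadth distributions, annotation
richness of real ontologies, or unicode content. Passing tests on
generated graphs therefore demonstrate contract correctness — parsing,
round-trips, traversal, search algebra — not robustness to every
real-world authoring quirk.

## Problem sizes and numerical choices

The test suite uses graph sizes chosen to exercise the algorithms while
keeping the default run fast: 25 graphs of 60–300 terms for round-trip
and dialect invariance, 50 graphs of up to 50 terms for the
transitive-closure oracle (boolean matrix powers — an independent
implementation kept deliberately separate from the work-list code it
checks), 100 random queries per fixture for search algebra, and
TOY + three 30-term fixtures for loopback REST equality. There is no
floating-point component anywhere: all comparisons in tests are
bit-exact (`identical()`).

Degenerate inputs are defined behaviour: an empty OBO document parses
to an empty graph with a missing-header warning; an empty service lists
no ontologies; absent terms and ontologies are `NULL` results for
lookups and typed errors for operations that require existence;
whitespace-only queries are invalid-query errors.

## Known limitations

- OBO trailing modifiers (`{...}`) are not interpreted; logical tags
  are preserved, not reasoned over.
- Only RDF/XML OWL is read; other serializations are out of scope.
- Which exact OBO tag set survives an OBO-to-OWL trip is pinned
  explicitly (labels, synonyms, definitions, `is_a`, xrefs, obsolete);
  anything else is OBO-side only.
- One canonical root path is reported under multiple inheritance.
- No term-level versioning is stored; ontology-level version strings
  are carried through from headers.
- The cross-ontology accession index is first-wins on collision —
  convenient for OBO-style unique identifiers, unsafe in principle for
  OWL namespaces, hence the warning and the two-argument `get_term()`.
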