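# The ontology-service contract. Every backend (local files, HTTP client)
# and every decorator implements the single generic `service_invoke`;
# the 16 user-facing operations below are thin wrappers that validate
# arguments and delegate. That keeps the decorator pattern honest: a
# decorator intercepts one function, not sixteen.

# Operation registry: "list" operations return lists of terms/records and
# fan out under composition; "single" operations return one value (or
# NULL for absent) and take the first answer.
ONTO_OPS <- list(
  list_ontologies = "list",
  get_ontology    = "single",
  search_all      = "search",
  search_ontology = "search",
  get_term        = "single",
  get_all_terms   = "list",
  get_annotations = "single",
  get_synonyms    = "single",
  get_definitions = "single",
  get_root_terms  = "list",
  get_children    = "list",
  get_parents     = "list",
  get_all_children = "list",
  get_all_parents = "list",
  get_term_path   = "list",
  get_relations   = "single"
)

#' Invoke a service operation by name
#'
#' The dispatch point of the service contract. Backends and decorators
#' provide methods; user code normally calls the named wrappers
#' ([search_all()], [get_term()], ...) instead.
#'
#' @param service An `ontology_service` object.
#' @param op Operation name; one of `names(ONTO_OPS)`.
#' @param args Named list of canonical arguments.
#' @return The operation's result.
#' @keywords internal
#' @export
service_invoke <- function(service, op, args = list()) {
  UseMethod("service_invoke")
}

#' @export
service_invoke.default <- function(service, op, args = list()) {
  stop("not an ontology service: ", paste(class(service), collapse = "/"))
}

#' @export
print.ontology_service <- function(x, ...) {
  cat(sprintf("<%s>\n", class(x)[[1L]]))
  invisible(x)
}

term_args <- function(term) {
  stopifnot(inherits(term, "ontology_term"))
  list(ontology_accession = term$ontology_accession,
       term_accession = term$accession)
}

check_query <- function(query) {
  if (!is.character(query) || length(query) != 1L || !nzchar(trimws(query)))
    stop_invalid_query()
  query
}

#' List the ontologies a service knows about
#'
#' @param service An `ontology_service`.
#' @return List of [ontology_record()]s, sorted by ontology accession.
#' @export
list_ontologies <- function(service)
  service_invoke(service, "list_ontologies")

#' Fetch one ontology's metadata record
#'
#' @param service An `ontology_service`.
#' @param ontology_accession Ontology accession (case-sensitive).
#' @return An [ontology_record()], or `NULL` when the ontology is unknown
#'   (absence is a result, not an error).
#' @export
get_ontology <- function(service, ontology_accession)
  service_invoke(service, "get_ontology",
                 list(ontology_accession = ontology_accession))

#' Search every ontology of a service
#'
#' Candidate strings are term labels and, when
#' `options$include_properties`, synonym texts, definition texts and all
#' other string annotation values. Exact search means case-insensitive
#' full-string equality; non-exact means case-insensitive substring
#' containment. Obsolete terms are excluded unless
#' `options$include_obsolete`. Results are ordered by ontology accession,
#' then term accession.
#'
#' @param service An `ontology_service`.
#' @param query Keyword; must be non-empty after trimming.
#' @param options A [search_options()].
#' @return List of [ontology_term()]s.
#' @export
search_all <- function(service, query, options = search_options())
  service_invoke(service, "search_all",
                 list(query = check_query(query), options = options))

#' Search a single ontology
#'
#' As [search_all()], restricted to one ontology; an unknown ontology
#' accession raises an ontology-not-found error.
#'
#' @inheritParams search_all
#' @param ontology_accession Ontology accession.
#' @return List of [ontology_term()]s.
#' @export
search_ontology <- function(service, ontology_accession, query,
                            options = search_options())
  service_invoke(service, "search_ontology",
                 list(ontology_accession = ontology_accession,
                      query = check_query(query), options = options))

#' Look up a term by accession
#'
#' With an ontology accession the lookup is exact in that ontology. With
#' `ontology_accession = NULL` a cross-ontology accession index is
#' consulted (first loaded ontology wins when two ontologies share an
#' accession).
#'
#' @param service An `ontology_service`.
#' @param term_accession Term accession (case-sensitive).
#' @param ontology_accession Ontology accession, or `NULL` for the index
#'   variant.
#' @return An [ontology_term()], or `NULL` when absent.
#' @export
get_term <- function(service, term_accession, ontology_accession = NULL)
  service_invoke(service, "get_term",
                 list(ontology_accession = ontology_accession,
                      term_accession = term_accession))

#' All terms of an ontology
#'
#' @param service An `ontology_service`.
#' @param ontology_accession Ontology accession.
#' @return List of every [ontology_term()] (obsolete ones included,
#'   flagged), sorted by accession.
#' @export
get_all_terms <- function(service, ontology_accession)
  service_invoke(service, "get_all_terms",
                 list(ontology_accession = ontology_accession))

#' Raw annotation set of a term
#'
#' The full raw annotation map, including scoped synonym raw forms and
#' cross-reference lists — nothing is stripped at this level.
#'
#' @param service An `ontology_service`.
#' @param term An [ontology_term()].
#' @return Named list of character vectors.
#' @export
get_annotations <- function(service, term)
  service_invoke(service, "get_annotations", term_args(term))

#' Synonyms of a term, stripped to bare text
#'
#' Scope qualifiers and cross-references are stripped for consistency
#' across backends; the raw scoped forms remain available through
#' [get_annotations()].
#'
#' @inheritParams get_annotations
#' @return Character vector, deduplicated and sorted.
#' @export
get_synonyms <- function(service, term)
  service_invoke(service, "get_synonyms", term_args(term))

#' Definitions of a term, stripped to bare text
#'
#' @inheritParams get_annotations
#' @return Character vector of definition texts (xrefs stripped).
#' @export
get_definitions <- function(service, term)
  service_invoke(service, "get_definitions", term_args(term))

#' Root terms of an ontology
#'
#' @param service An `ontology_service`.
#' @param ontology_accession Ontology accession.
#' @return List of non-obsolete [ontology_term()]s with no parent, sorted
#'   by accession.
#' @export
get_root_terms <- function(service, ontology_accession)
  service_invoke(service, "get_root_terms",
                 list(ontology_accession = ontology_accession))

#' Direct children of a term
#' @inheritParams get_annotations
#' @return List of [ontology_term()]s, sorted by accession.
#' @export
get_children <- function(service, term)
  service_invoke(service, "get_children", term_args(term))

#' Direct parents of a term
#' @inheritParams get_annotations
#' @return List of [ontology_term()]s, sorted by accession.
#' @export
get_parents <- function(service, term)
  service_invoke(service, "get_parents", term_args(term))

#' All descendants of a term
#' @inheritParams get_annotations
#' @return List of [ontology_term()]s, sorted by accession.
#' @export
get_all_children <- function(service, term)
  service_invoke(service, "get_all_children", term_args(term))

#' All ancestors of a term
#' @inheritParams get_annotations
#' @return List of [ontology_term()]s, sorted by accession.
#' @export
get_all_parents <- function(service, term)
  service_invoke(service, "get_all_parents", term_args(term))

#' Canonical path from the root to a term
#'
#' Root first; at multi-parent steps the lexicographically smallest
#' parent is chosen. A cycle on the chosen path raises a
#' cyclic-hierarchy error.
#'
#' @inheritParams get_annotations
#' @return List of [ontology_term()]s, root first, the term itself last.
#' @export
get_term_path <- function(service, term)
  service_invoke(service, "get_term_path", term_args(term))

#' Typed relations and cross-references of a term
#'
#' @inheritParams get_annotations
#' @return Named list: one entry per relation name with target
#'   [ontology_term()]s (raw strings when the target is not resolvable),
#'   plus an `xref` entry with raw cross-reference strings when present.
#' @export
get_relations <- function(service, term)
  service_invoke(service, "get_relations", term_args(term))
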