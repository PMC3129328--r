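# Condition constructors. Every package error carries a subclass of
# "onto_error" so callers (and the REST layer) can map failures to
# behaviour without parsing messages.

onto_error <- function(class, message, ...) {
  structure(
    class = c(class, "onto_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

stop_term_not_found <- function(term_accession, ontology_accession = NULL) {
  where <- if (is.null(ontology_accession)) "" else
    sprintf(" in ontology '%s'", ontology_accession)
  stop(onto_error(
    "onto_term_not_found",
    sprintf("term '%s' not found%s", term_accession, where),
    term_accession = term_accession,
    ontology_accession = ontology_accession
  ))
}

stop_ontology_not_found <- function(ontology_accession) {
  stop(onto_error(
    "onto_ontology_not_found",
    sprintf("ontology '%s' not found", ontology_accession),
    ontology_accession = ontology_accession
  ))
}

stop_cyclic_hierarchy <- function(accession) {
  stop(onto_error(
    "onto_cyclic_hierarchy",
    sprintf("cyclic is_a hierarchy: accession '%s' revisited on path to root",
            accession),
    accession = accession
  ))
}

stop_invalid_query <- function() {
  stop(onto_error("onto_invalid_query",
                  "search query is empty after trimming whitespace"))
}

stop_malformed <- function(message, line = NULL) {
  at <- if (is.null(line)) "" else sprintf(" (line %d)", line)
  stop(onto_error("onto_malformed", paste0(message, at), line = line))
}

stop_service_unavailable <- function(message) {
  stop(onto_error("onto_service_unavailable", message))
}

stop_translation_error <- function(message) {
  stop(onto_error("onto_translation_error", message))
}
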