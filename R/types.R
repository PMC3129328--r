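#' Construct an ontology term
#'
#' A term is the unit every service operation traffics in: a tuple of term
#' accession, term label, and the accession of the ontology it belongs to.
#' The identity key is the pair (ontology accession, term accession); the
#' label is carried for convenience only and plays no part in equality.
#'
#' @param accession Compact term identifier, e.g. `"GO:0043227"`. Must be
#'   non-empty.
#' @param label Human-readable label; may be the empty string.
#' @param ontology_accession Accession of the owning ontology, e.g. `"GO"`.
#' @param uri Optional full URI of the term, or `NULL`.
#' @param obsolete Logical obsolescence flag.
#' @return An object of class `ontology_term`.
#' @examples
#' ontology_term("GO:0043227", "membrane-bounded organelle", "GO")
#' @export
ontology_term <- function(accession, label = "", ontology_accession = "",
                          uri = NULL, obsolete = FALSE) {
  stopifnot(is.character(accession), length(accession) == 1L,
            nzchar(accession))
  structure(
    list(accession = accession,
         label = as.character(label)[1L],
         ontology_accession = as.character(ontology_accession)[1L],
         uri = if (is.null(uri)) NULL else as.character(uri)[1L],
         obsolete = isTRUE(obsolete)),
    class = "ontology_term"
  )
}

#' @export
print.ontology_term <- function(x, ...) {
  flag <- if (x$obsolete) " [obsolete]" else ""
  cat(sprintf("<ontology_term> %s \"%s\" (%s)%s\n",
              x$accession, x$label, x$ontology_accession, flag))
  invisible(x)
}

# Identity key: (ontology_accession, accession).
term_key <- function(term) paste(term$ontology_accession, term$accession,
                                 sep = "\r")

#' @export
`==.ontology_term` <- function(e1, e2) {
  inherits(e1, "ontology_term") && inherits(e2, "ontology_term") &&
    term_key(e1) == term_key(e2)
}

#' Convert a list of terms to a data frame
#'
#' @param terms A list of [ontology_term()] objects.
#' @return A data frame with columns `accession`, `label`,
#'   `ontology_accession`, `obsolete`.
#' @export
terms_as_data_frame <- function(terms) {
  data.frame(
    accession = vapply(terms, function(t) t$accession, character(1)),
    label = vapply(terms, function(t) t$label, character(1)),
    ontology_accession =
      vapply(terms, function(t) t$ontology_accession, character(1)),
    obsolete = vapply(terms, function(t) t$obsolete, logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Construct an ontology-level metadata record
#'
#' @param accession Ontology accession (unique within a service).
#' @param name Ontology name; free text.
#' @param version Free-text version string, possibly empty.
#' @param release_date Optional `Date` (or `NULL`).
#' @param format One of `"OBO"`, `"OWL"`, `"REMOTE"`.
#' @param term_count Number of terms the ontology holds (including obsolete
#'   ones); must equal the length of `get_all_terms()` for that ontology.
#' @return An object of class `ontology_record`.
#' @export
ontology_record <- function(accession, name = "", version = "",
                            release_date = NULL, format = c("OBO", "OWL", "REMOTE"),
                            term_count = 0L) {
  format <- match.arg(format)
  stopifnot(is.character(accession), length(accession) == 1L,
            nzchar(accession), term_count >= 0)
  structure(
    list(accession = accession, name = as.character(name)[1L],
         version = as.character(version)[1L],
         release_date = release_date, format = format,
         term_count = as.integer(term_count)),
    class = "ontology_record"
  )
}

#' @export
print.ontology_record <- function(x, ...) {
  cat(sprintf("<ontology_record> %s \"%s\" (%s, %d terms, version \"%s\")\n",
              x$accession, x$name, x$format, x$term_count, x$version))
  invisible(x)
}

#' Construct a synonym value
#'
#' OBO synonyms carry a scope qualifier (how close the synonym is to the
#' term's meaning) and optional cross-references to the synonym's origin.
#' Service-level [get_synonyms()] strips both down to the bare text; the
#' scoped form stays reachable through [get_annotations()].
#'
#' @param text Unquoted, unescaped synonym string.
#' @param scope One of `"EXACT"`, `"BROAD"`, `"NARROW"`, `"RELATED"`,
#'   `"UNSPECIFIED"`.
#' @param xrefs Character vector of cross-reference identifiers.
#' @return An object of class `synonym_value`.
#' @export
synonym_value <- function(text, scope = "UNSPECIFIED", xrefs = character()) {
  scope <- match.arg(scope,
                     c("UNSPECIFIED", "EXACT", "BROAD", "NARROW", "RELATED"))
  structure(list(text = text, scope = scope, xrefs = as.character(xrefs)),
            class = "synonym_value")
}

#' Construct a definition value
#'
#' @param text Definition text (non-empty).
#' @param xrefs Character vector of cross-references backing the definition.
#' @return An object of class `definition_value`.
#' @export
definition_value <- function(text, xrefs = character()) {
  structure(list(text = text, xrefs = as.character(xrefs)),
            class = "definition_value")
}

#' Search options
#'
#' The three independent knobs every search operation accepts.
#'
#' @param exact If `TRUE`, match by case-insensitive full-string equality;
#'   otherwise by case-insensitive substring containment.
#' @param include_properties If `TRUE`, candidate strings include synonym
#'   texts, definition texts, and every other string annotation value, in
#'   addition to the label.
#' @param include_obsolete If `TRUE`, obsolete terms may appear in results.
#' @return An object of class `search_options`.
#' @export
search_options <- function(exact = FALSE, include_properties = FALSE,
                           include_obsolete = FALSE) {
  structure(list(exact = isTRUE(exact),
                 include_properties = isTRUE(include_properties),
                 include_obsolete = isTRUE(include_obsolete)),
            class = "search_options")
}

#' Label-resolution policy for OWL sources
#'
#' When reading OWL, a term's label is resolved in order of preference:
#' each user-specified annotation property URI in turn, then `rdfs:label`,
#' then `skos:prefLabel`, and finally the fragment of the class URI, which
#' always exists, so resolution is total.
#'
#' @param user_property_uris Ordered character vector of absolute
#'   annotation-property URIs tried before the standard ones; may be empty.
#' @return An object of class `label_policy`.
#' @export
label_policy <- function(user_property_uris = character()) {
  user_property_uris <- as.character(user_property_uris)
  if (length(user_property_uris) &&
      !all(grepl("^[A-Za-z][A-Za-z0-9+.-]*:", user_property_uris))) {
    stop("user_property_uris must be absolute URIs")
  }
  structure(list(user_property_uris = user_property_uris),
            class = "label_policy")
}

#' Identifier-namespace mapping rule
#'
#' One rule of the accession-translation decorator: a match pattern that
#' recognises identifiers belonging to a namespace, plus rewrite rules
#' (applied with [gsub()]) for term and ontology accessions. The classic
#' case is bridging OWL-style `NCBITaxon_1` and OBO-style `NCBITaxon:1`.
#'
#' @param match_pattern Regular expression; an identifier is translated by
#'   the first rule whose pattern matches it.
#' @param term_rewrite Length-2 character vector `c(pattern, replacement)`
#'   applied to the term accession, or `NULL` for no rewrite.
#' @param ontology_rewrite As `term_rewrite`, for the ontology accession.
#' @return An object of class `ontology_id_mapping`.
#' @examples
#' ontology_id_mapping("^NCBITaxon_\\d+$", term_rewrite = c("_", ":"))
#' @export
ontology_id_mapping <- function(match_pattern, term_rewrite = NULL,
                                ontology_rewrite = NULL) {
  # fail fast if the pattern does not compile
  grepl(match_pattern, "")
  check_rw <- function(rw, what) {
    if (!is.null(rw) && (!is.character(rw) || length(rw) != 2L))
      stop(sprintf("%s must be NULL or c(pattern, replacement)", what))
  }
  check_rw(term_rewrite, "term_rewrite")
  check_rw(ontology_rewrite, "ontology_rewrite")
  structure(list(match_pattern = match_pattern,
                 term_rewrite = term_rewrite,
                 ontology_rewrite = ontology_rewrite),
            class = "ontology_id_mapping")
}
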