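# OWL reader/writer over RDF/XML. Scope is deliberately assertion-level:
# named classes, asserted subclass axioms between named classes, and
# annotation values. No reasoning, no imports closure, no restriction
# semantics. Two writer dialects exist so the same graph can be emitted
# with SKOS annotation properties or with OBO-in-OWL ones.

OWL_NS <- c(
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#",
  skos = "http://www.w3.org/2004/02/skos/core#",
  oio  = "http://www.geneontology.org/formats/oboInOwl#"
)

URI_RDFS_LABEL <- paste0(OWL_NS[["rdfs"]], "label")
URI_SKOS_PREFLABEL <- paste0(OWL_NS[["skos"]], "prefLabel")
URI_SKOS_ALTLABEL <- paste0(OWL_NS[["skos"]], "altLabel")
URI_SKOS_DEFINITION <- paste0(OWL_NS[["skos"]], "definition")
URI_OWL_DEPRECATED <- paste0(OWL_NS[["owl"]], "deprecated")
URI_OIO_DBXREF <- paste0(OWL_NS[["oio"]], "hasDbXref")
URI_OIO_DEFINITION <- paste0(OWL_NS[["oio"]], "hasDefinition")

# OBO-in-OWL synonym properties, pinned set; hasSynonym carries synonyms
# whose scope is unknown.
OIO_SYNONYM_URIS <- c(
  EXACT = paste0(OWL_NS[["oio"]], "hasExactSynonym"),
  BROAD = paste0(OWL_NS[["oio"]], "hasBroadSynonym"),
  NARROW = paste0(OWL_NS[["oio"]], "hasNarrowSynonym"),
  RELATED = paste0(OWL_NS[["oio"]], "hasRelatedSynonym"),
  UNSPECIFIED = paste0(OWL_NS[["oio"]], "hasSynonym")
)

#' Derive a compact accession from a URI
#'
#' The substring after the last `#`; if the URI has no `#`, the substring
#' after the last `/`; the whole string when it contains neither.
#'
#' @param uri A non-empty URI string (vectorized).
#' @return Character vector of accessions.
#' @examples
#' accession_from_uri("http://sig.uw.edu/fma#Anatomical_entity")
#' accession_from_uri("http://purl.org/obo/NCBITaxon_1")
#' @export
accession_from_uri <- function(uri) {
  vapply(uri, function(u) {
    if (grepl("#", u, fixed = TRUE)) return(sub("^.*#", "", u))
    if (grepl("/", u, fixed = TRUE)) return(sub("^.*/", "", u))
    u
  }, character(1), USE.NAMES = FALSE)
}

#' Resolve a class label from its annotations
#'
#' Tries, in order of preference and availability: each user-specified
#' property URI of the policy, then `rdfs:label`, then `skos:prefLabel`,
#' and finally the fragment of the class URI — so the result is always
#' non-empty.
#'
#' @param annotations A named list of character vectors keyed by property
#'   URI (an annotation set).
#' @param uri The class URI.
#' @param policy A [label_policy()].
#' @return The resolved label string.
#' @export
resolve_label <- function(annotations, uri, policy = label_policy()) {
  for (p in c(policy$user_property_uris, URI_RDFS_LABEL,
              URI_SKOS_PREFLABEL)) {
    vals <- annotations[[p]]
    vals <- vals[nzchar(vals)]
    if (length(vals)) return(vals[[1L]])
  }
  accession_from_uri(uri)
}

ns_lookup <- function(nsmap, prefixed) {
  parts <- strsplit(prefixed, ":", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) return(parts[[1L]])  # no namespace
  paste0(nsmap[[parts[[1L]]]] %||% "", paste(parts[-1L], collapse = ":"))
}

#' Parse an OWL (RDF/XML) document into an ontology graph
#'
#' Every named class except `owl:Thing` (and obsolete-bucket classes whose
#' URI fragment is `ObsoleteClass`) becomes a term; asserted subclass
#' axioms between named classes feed the `is_a` hierarchy; annotation
#' values are collected keyed by full property URI. Synonyms are taken
#' from `skos:altLabel` and the OBO-in-OWL scoped synonym properties;
#' definitions from `skos:definition` and `oboInOwl:hasDefinition`;
#' cross-references from `oboInOwl:hasDbXref`. A class is obsolete when
#' `owl:deprecated` is true or when it sits (transitively) under an
#' `ObsoleteClass` bucket. When two class URIs share an accession the
#' first in document order wins and later ones are dropped with a warning.
#'
#' @param x Path to an RDF/XML file, or the document text.
#' @param policy A [label_policy()] for label resolution.
#' @param ontology_accession Optional accession override; otherwise the
#'   ontology IRI's final path segment, uppercased.
#' @return An [ontology_graph()].
#' @export
parse_owl <- function(x, policy = label_policy(),
                      ontology_accession = NULL) {
  doc <- tryCatch(xml2::read_xml(x),
                  error = function(e) stop_malformed(
                    paste0("cannot parse RDF/XML: ", conditionMessage(e))))
  nsmap <- tryCatch(xml2::xml_ns(doc), error = function(e) character())

  onto_node <- xml2::xml_find_first(doc, "//owl:Ontology", OWL_NS)
  onto_iri <- NA_character_
  if (!inherits(onto_node, "xml_missing"))
    onto_iri <- xml2::xml_text(
      xml2::xml_find_first(onto_node, "@rdf:about", OWL_NS))
  if (is.na(onto_iri) || !nzchar(onto_iri)) {
    warning("OWL document has no ontology header IRI", call. = FALSE)
    stem <- if (is.character(x) && length(x) == 1L && file.exists(x))
      tools::file_path_sans_ext(basename(x)) else "UNKNOWN"
    onto_iri <- stem
  }
  acc <- ontology_accession %||% toupper(accession_from_uri(onto_iri))
  version <- ""
  if (!inherits(onto_node, "xml_missing")) {
    v <- xml2::xml_find_first(onto_node, "./owl:versionInfo", OWL_NS)
    if (!inherits(v, "xml_missing")) version <- xml2::xml_text(v)
  }

  class_nodes <- xml2::xml_find_all(doc, "//owl:Class[@rdf:about]", OWL_NS)
  uris <- vapply(class_nodes, function(n)
    xml2::xml_text(xml2::xml_find_first(n, "@rdf:about", OWL_NS)),
    character(1))
  # keep top-level class declarations only (nested ones are edge targets)
  top <- vapply(class_nodes, function(n)
    xml2::xml_name(xml2::xml_parent(n)) == "RDF", logical(1))

  thing_uri <- paste0(OWL_NS[["owl"]], "Thing")

  terms <- list(); annotations <- list(); synonyms <- list()
  definitions <- list(); xrefs <- list(); uri_of <- character()
  sub_child <- character(); sub_parent <- character()  # URIs
  deprecated <- character()

  for (i in which(top)) {
    node <- class_nodes[[i]]
    uri <- uris[[i]]
    if (uri == thing_uri) next
    frag <- accession_from_uri(uri)
    term_acc <- frag
    is_obsolete_bucket <- identical(frag, "ObsoleteClass")
    ann <- list()
    for (child in xml2::xml_children(node)) {
      full <- ns_lookup(nsmap, xml2::xml_name(child, nsmap))
      if (full == paste0(OWL_NS[["rdfs"]], "subClassOf")) {
        res <- xml2::xml_find_first(child, "@rdf:resource", OWL_NS)
        target <- if (!inherits(res, "xml_missing")) xml2::xml_text(res)
        else {
          nested <- xml2::xml_find_first(child, "./owl:Class/@rdf:about",
                                         OWL_NS)
          if (!inherits(nested, "xml_missing")) xml2::xml_text(nested)
          else NA_character_   # restriction or anonymous: ignored
        }
        if (!is.na(target) && nzchar(target) && target != thing_uri) {
          sub_child <- c(sub_child, uri)
          sub_parent <- c(sub_parent, target)
        }
        next
      }
      if (full == paste0(OWL_NS[["rdf"]], "type")) next
      val <- xml2::xml_text(child)
      if (!nzchar(val)) {
        res <- xml2::xml_find_first(child, "@rdf:resource", OWL_NS)
        if (!inherits(res, "xml_missing")) val <- xml2::xml_text(res)
      }
      if (nzchar(val)) ann[[full]] <- c(ann[[full]], val)
    }
    if (is_obsolete_bucket) next
    if (term_acc %in% names(terms)) {
      warning(sprintf(
        "accession collision: '%s' (from %s) already defined; dropping",
        term_acc, uri), call. = FALSE)
      next
    }
    if (isTRUE(tolower(ann[[URI_OWL_DEPRECATED]][1L] %||% "") == "true"))
      deprecated <- c(deprecated, uri)

    syns <- list()
    for (scope in names(OIO_SYNONYM_URIS)) {
      for (v in ann[[OIO_SYNONYM_URIS[[scope]]]] %||% character())
        syns <- c(syns, list(synonym_value(v, scope = scope)))
    }
    for (v in ann[[URI_SKOS_ALTLABEL]] %||% character())
      syns <- c(syns, list(synonym_value(v, scope = "UNSPECIFIED")))
    defs <- lapply(c(ann[[URI_OIO_DEFINITION]] %||% character(),
                     ann[[URI_SKOS_DEFINITION]] %||% character()),
                   definition_value)
    xr <- ann[[URI_OIO_DBXREF]] %||% character()

    terms[[term_acc]] <- ontology_term(
      term_acc, resolve_label(ann, uri, policy), acc, uri = uri)
    uri_of[[uri]] <- term_acc
    if (length(ann)) annotations[[term_acc]] <- ann
    if (length(syns)) synonyms[[term_acc]] <- syns
    if (length(defs)) definitions[[term_acc]] <- defs
    if (length(xr)) xrefs[[term_acc]] <- xr
  }

  # obsolete: deprecated classes, plus everything transitively under an
  # ObsoleteClass bucket (those edges do not enter the hierarchy)
  bucket_uris <- unique(
    uris[vapply(uris, function(u)
      identical(accession_from_uri(u), "ObsoleteClass"), logical(1))])
  subtree <- bucket_uris
  repeat {
    grown <- union(subtree, sub_child[sub_parent %in% subtree])
    if (length(grown) == length(subtree)) break
    subtree <- grown
  }
  obsolete_uris <- union(deprecated, subtree)
  for (u in intersect(obsolete_uris, names(uri_of))) {
    a <- uri_of[[u]]
    terms[[a]]$obsolete <- TRUE
  }

  keep <- sub_child %in% names(uri_of) & sub_parent %in% names(uri_of) &
    !vapply(sub_parent, function(u)
      identical(accession_from_uri(u), "ObsoleteClass"), logical(1))
  is_a <- unique(data.frame(
    child = unname(uri_of[sub_child[keep]]),
    parent = unname(uri_of[sub_parent[keep]]),
    stringsAsFactors = FALSE))
  is_a <- is_a[is_a$child != is_a$parent, , drop = FALSE]

  record <- ontology_record(accession = acc, name = acc, version = version,
                            format = "OWL", term_count = length(terms))
  ontology_graph(record, terms = terms, annotations = annotations,
                 synonyms = synonyms, definitions = definitions,
                 is_a = is_a, xrefs = xrefs,
                 graph_annotations = list(ontology_iri = onto_iri))
}

# --- writer ------------------------------------------------------------

xml_escape_text <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

xml_escape_attr <- function(s) gsub("\"", "&quot;", xml_escape_text(s),
                                    fixed = TRUE)

owl_base_uri <- function(graph) {
  graph$graph_annotations$ontology_iri %||%
    paste0("http://example.org/ontology/", tolower(graph$metadata$accession))
}

term_uri_for <- function(graph, accession, base) {
  graph$terms[[accession]]$uri %||% paste0(base, "#", accession)
}

#' Write an ontology graph as RDF/XML OWL
#'
#' Two annotation dialects are supported. `"SKOS"` uses
#' `skos:prefLabel`/`skos:altLabel`/`skos:definition`; `"OBOINOWL"` uses
#' `rdfs:label` plus the OBO-in-OWL scoped synonym and definition
#' properties (synonym scopes survive this dialect only). Both emit
#' cross-references as `oboInOwl:hasDbXref` and obsolescence as
#' `owl:deprecated`. Parsing the output reproduces the graph on the
#' normalized view (labels, synonym texts, definition texts, `is_a`
#' edges, obsolete flags, xrefs). Typed relations other than `is_a` are
#' not represented in OWL output.
#'
#' @param graph An [ontology_graph()].
#' @param path Output file path.
#' @param dialect `"SKOS"` or `"OBOINOWL"`.
#' @return `path`, invisibly.
#' @export
write_owl <- function(graph, path, dialect = c("SKOS", "OBOINOWL")) {
  dialect <- match.arg(dialect)
  base <- owl_base_uri(graph)
  prop <- function(tag, value)
    sprintf("    <%s>%s</%s>", tag, xml_escape_text(value), tag)

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<rdf:RDF",
    sprintf("    xmlns:%s=\"%s\"",
            c("rdf", "rdfs", "owl", "skos", "oboInOwl"),
            unname(OWL_NS[c("rdf", "rdfs", "owl", "skos", "oio")])),
    ">",
    sprintf("  <owl:Ontology rdf:about=\"%s\">", xml_escape_attr(base)),
    if (nzchar(graph$metadata$version))
      prop("owl:versionInfo", graph$metadata$version),
    "  </owl:Ontology>"
  )

  for (acc in sort_c(names(graph$terms))) {
    t <- graph$terms[[acc]]
    uri <- term_uri_for(graph, acc, base)
    body <- character()
    if (nzchar(t$label)) {
      body <- c(body, if (dialect == "SKOS") prop("skos:prefLabel", t$label)
                else prop("rdfs:label", t$label))
    }
    for (sv in graph$synonyms[[acc]] %||% list()) {
      body <- c(body, if (dialect == "SKOS") prop("skos:altLabel", sv$text)
                else {
                  local_name <- sub(OWL_NS[["oio"]], "oboInOwl:",
                                    OIO_SYNONYM_URIS[[sv$scope]], fixed = TRUE)
                  prop(local_name, sv$text)
                })
    }
    for (dv in graph$definitions[[acc]] %||% list()) {
      body <- c(body, if (dialect == "SKOS") prop("skos:definition", dv$text)
                else prop("oboInOwl:hasDefinition", dv$text))
    }
    for (x in graph$xrefs[[acc]] %||% character())
      body <- c(body, prop("oboInOwl:hasDbXref", x))
    if (t$obsolete)
      body <- c(body, paste0(
        "    <owl:deprecated rdf:datatype=",
        "\"http://www.w3.org/2001/XMLSchema#boolean\">true",
        "</owl:deprecated>"))
    for (p in sort_c(graph$is_a$parent[graph$is_a$child == acc]))
      body <- c(body, sprintf(
        "    <rdfs:subClassOf rdf:resource=\"%s\"/>",
        xml_escape_attr(term_uri_for(graph, p, base))))
    lines <- c(lines,
               sprintf("  <owl:Class rdf:about=\"%s\">",
                       xml_escape_attr(uri)),
               body,
               "  </owl:Class>")
  }
  lines <- c(lines, "</rdf:RDF>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
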