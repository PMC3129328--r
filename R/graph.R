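#' In-memory ontology graph
#'
#' The internal model every backend parses into and every traversal runs
#' on: terms keyed by accession, raw annotation sets, parsed synonyms and
#' definitions, typed directed edges, and cross-references. Only `is_a`
#' edges define the hierarchy used by parents/children/ancestors/
#' descendants/path/roots; all other relations (`part_of` etc.) live in
#' `relations` and are exposed only through [get_relations()].
#'
#' @param metadata An [ontology_record()].
#' @param terms Named list mapping accession to [ontology_term()].
#' @param annotations Named list mapping accession to an annotation set (a
#'   named list of non-empty character vectors).
#' @param synonyms Named list mapping accession to a list of
#'   [synonym_value()] objects.
#' @param definitions Named list mapping accession to a list of
#'   [definition_value()] objects.
#' @param is_a Data frame with character columns `child`, `parent`; one
#'   row per asserted subsumption edge.
#' @param relations Data frame with character columns `subject`,
#'   `relation`, `object`.
#' @param xrefs Named list mapping accession to a character vector of
#'   cross-references.
#' @param graph_annotations Named list of ontology-level annotations
#'   (header tags, typedef stanzas).
#' @return An object of class `ontology_graph`.
#' @export
ontology_graph <- function(metadata,
                           terms = list(),
                           annotations = list(),
                           synonyms = list(),
                           definitions = list(),
                           is_a = empty_edges(),
                           relations = empty_relations(),
                           xrefs = list(),
                           graph_annotations = list()) {
  g <- structure(
    list(metadata = metadata, terms = terms, annotations = annotations,
         synonyms = synonyms, definitions = definitions,
         is_a = is_a, relations = relations, xrefs = xrefs,
         graph_annotations = graph_annotations),
    class = "ontology_graph"
  )
  validate_ontology_graph(g)
}

empty_edges <- function() {
  data.frame(child = character(), parent = character(),
             stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(subject = character(), relation = character(),
             object = character(), stringsAsFactors = FALSE)
}

validate_ontology_graph <- function(g) {
  accs <- names(g$terms)
  for (a in accs) {
    if (!identical(g$terms[[a]]$accession, a))
      stop(sprintf("graph term keyed '%s' carries accession '%s'",
                   a, g$terms[[a]]$accession))
  }
  ends <- unique(c(g$is_a$child, g$is_a$parent))
  missing <- setdiff(ends, accs)
  if (length(missing))
    stop(sprintf("is_a edge endpoint(s) not in term set: %s",
                 paste(missing, collapse = ", ")))
  if (any(g$is_a$child == g$is_a$parent))
    stop("is_a edges must not contain self-loops")
  # term_count in the record tracks the term map
  g$metadata$term_count <- length(g$terms)
  g
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph> %s: %d terms, %d is_a edges, %d obsolete\n",
              x$metadata$accession, length(x$terms), nrow(x$is_a),
              sum(vapply(x$terms, function(t) t$obsolete, logical(1)))))
  invisible(x)
}

assert_in_graph <- function(graph, accession) {
  if (!accession %in% names(graph$terms))
    stop_term_not_found(accession, graph$metadata$accession)
}

#' Direct parents of a term
#'
#' @param graph An [ontology_graph()].
#' @param accession Term accession present in `graph`.
#' @return Character vector of parent accessions, sorted lexicographically.
#' @export
direct_parents <- function(graph, accession) {
  assert_in_graph(graph, accession)
  sort_c(unique(graph$is_a$parent[graph$is_a$child == accession]))
}

#' Direct children of a term
#'
#' @inheritParams direct_parents
#' @return Character vector of child accessions, sorted lexicographically.
#' @export
direct_children <- function(graph, accession) {
  assert_in_graph(graph, accession)
  sort_c(unique(graph$is_a$child[graph$is_a$parent == accession]))
}

# Iterative reachability over is_a edges; direction "up" follows
# child -> parent, "down" parent -> child. Explicit work-list, each node
# enters the visited set once, so cyclic inputs terminate.
reachable <- function(graph, accession, direction) {
  assert_in_graph(graph, accession)
  from <- if (direction == "up") graph$is_a$child else graph$is_a$parent
  to   <- if (direction == "up") graph$is_a$parent else graph$is_a$child
  visited <- character()
  worklist <- accession
  while (length(worklist)) {
    cur <- worklist[[1L]]
    worklist <- worklist[-1L]
    nxt <- to[from == cur]
    new <- setdiff(nxt, c(visited, accession))
    visited <- c(visited, new)
    worklist <- c(worklist, setdiff(new, worklist))
  }
  sort_c(unique(visited))
}

#' All ancestors of a term
#'
#' Every accession reachable by repeatedly following `is_a` edges upward,
#' excluding the start term. Implemented with an explicit work-list (no
#' call-stack recursion); terminates on cyclic input.
#'
#' @inheritParams direct_parents
#' @return Character vector of accessions, sorted lexicographically.
#' @export
ancestors <- function(graph, accession) reachable(graph, accession, "up")

#' All descendants of a term
#'
#' Mirror of [ancestors()] with edges followed downward.
#'
#' @inheritParams direct_parents
#' @return Character vector of accessions, sorted lexicographically.
#' @export
descendants <- function(graph, accession) reachable(graph, accession, "down")

#' Canonical path from the root to a term
#'
#' Walks upward from `accession`, at each step choosing the
#' lexicographically smallest parent when there are several, and returns
#' the path ordered root first. A visited set guards the walk: if the
#' chosen path revisits an accession a cyclic-hierarchy error is raised
#' naming the repeated accession.
#'
#' @inheritParams direct_parents
#' @return Character vector `c(root, ..., accession)`.
#' @export
path_to_root <- function(graph, accession) {
  assert_in_graph(graph, accession)
  path <- accession
  visited <- accession
  cur <- accession
  repeat {
    parents <- direct_parents(graph, cur)
    if (!length(parents)) break
    nxt <- parents[[1L]]  # lexicographically smallest: direct_parents sorts
    if (nxt %in% visited) stop_cyclic_hierarchy(nxt)
    path <- c(nxt, path)
    visited <- c(visited, nxt)
    cur <- nxt
  }
  path
}

#' Root terms of a graph
#'
#' @param graph An [ontology_graph()].
#' @return Accessions of all non-obsolete terms with no outgoing `is_a`
#'   edge, sorted lexicographically.
#' @export
root_accessions <- function(graph) {
  accs <- names(graph$terms)
  has_parent <- accs %in% graph$is_a$child
  obsolete <- vapply(graph$terms, function(t) t$obsolete, logical(1))
  sort_c(accs[!has_parent & !obsolete])
}

# locale-independent lexicographic sort (C collation), so orderings are
# reproducible across machines
sort_c <- function(x) {
  if (!length(x)) return(character())
  x[order(method = "radix", x)]
}

# The view on which OBO and both OWL dialects must agree: labels, synonym
# texts, definition texts, is_a edges, obsolete flags, xrefs.
normalized_view <- function(g) {
  accs <- sort_c(names(g$terms))
  list(
    ontology = g$metadata$accession,
    terms = lapply(
      stats::setNames(accs, accs),
      function(a) {
        t <- g$terms[[a]]
        list(
          label = t$label,
          obsolete = t$obsolete,
          synonyms = sort_c(vapply(g$synonyms[[a]] %||% list(),
                                   function(s) s$text, character(1))),
          definitions = sort_c(vapply(g$definitions[[a]] %||% list(),
                                      function(d) d$text, character(1))),
          xrefs = sort_c(g$xrefs[[a]] %||% character())
        )
      }),
    is_a = {
      e <- g$is_a[order(g$is_a$child, g$is_a$parent, method = "radix"), ,
                  drop = FALSE]
      rownames(e) <- NULL
      e
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
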