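#' Ontology service over local OBO/OWL files
#'
#' Parses each input into an in-memory [ontology_graph()] and serves the
#' full operation contract over the collection. An in-memory
#' cross-ontology accession index supports term lookup without naming the
#' ontology; when two loaded ontologies share a term accession the first
#' one loaded wins and a warning is logged.
#'
#' @param inputs Character vector of file paths (`.obo`, or RDF/XML OWL),
#'   or a list mixing paths and ready-made [ontology_graph()] objects.
#' @param policy A [label_policy()] applied to OWL inputs.
#' @param accession_overrides Optional character vector parallel to
#'   `inputs` (`NA` entries mean no override) forcing each ontology's
#'   accession.
#' @return An object of classes `file_service`, `ontology_service`.
#' @examples
#' svc <- file_service(list(toy_graph()))
#' length(search_all(svc, "cell"))
#' @export
file_service <- function(inputs, policy = label_policy(),
                         accession_overrides = NULL) {
  if (!is.list(inputs)) inputs <- as.list(inputs)
  if (!is.null(accession_overrides) &&
      length(accession_overrides) != length(inputs))
    stop("accession_overrides must be parallel to inputs")
  graphs <- list()
  index <- character()   # term accession -> ontology accession, first wins
  for (i in seq_along(inputs)) {
    input <- inputs[[i]]
    override <- if (is.null(accession_overrides)) NULL else {
      o <- accession_overrides[[i]]
      if (is.na(o)) NULL else o
    }
    g <- if (inherits(input, "ontology_graph")) {
      if (!is.null(override)) {
        input$metadata$accession <- override
        input$terms <- lapply(input$terms, function(t) {
          t$ontology_accession <- override
          t
        })
      }
      input
    } else if (is.character(input) && length(input) == 1L) {
      if (!file.exists(input))
        stop(sprintf("input file does not exist: %s", input))
      if (grepl("\\.obo$", input, ignore.case = TRUE))
        parse_obo(input, ontology_accession = override)
      else if (grepl("\\.(owl|rdf|xml)$", input, ignore.case = TRUE))
        parse_owl(input, policy = policy, ontology_accession = override)
      else if (startsWith(trimws(readLines(input, n = 1L, warn = FALSE)), "<"))
        parse_owl(input, policy = policy, ontology_accession = override)
      else
        parse_obo(input, ontology_accession = override)
    } else {
      stop("inputs must be file paths or ontology_graph objects")
    }
    acc <- g$metadata$accession
    if (acc %in% names(graphs))
      stop(sprintf("duplicate ontology accession '%s'", acc))
    graphs[[acc]] <- g
    for (t in names(g$terms)) {
      if (t %in% names(index)) {
        warning(sprintf(
          "term accession collision in index: '%s' in '%s' and '%s'; keeping the first",
          t, index[[t]], acc), call. = FALSE)
      } else {
        index[[t]] <- acc
      }
    }
  }
  structure(list(graphs = graphs, index = index),
            class = c("file_service", "ontology_service"))
}

fs_graph <- function(service, ontology_accession) {
  if (is.null(ontology_accession) ||
      !ontology_accession %in% names(service$graphs))
    stop_ontology_not_found(ontology_accession %||% "<null>")
  service$graphs[[ontology_accession]]
}

fs_resolve <- function(service, ontology_accession, term_accession) {
  g <- fs_graph(service, ontology_accession)
  if (!term_accession %in% names(g$terms))
    stop_term_not_found(term_accession, ontology_accession)
  g
}

materialize <- function(graph, accessions) {
  lapply(accessions, function(a) graph$terms[[a]])
}

# Candidate strings for search matching under the given options.
search_candidates <- function(graph, accession, options) {
  t <- graph$terms[[accession]]
  cand <- t$label
  if (options$include_properties) {
    cand <- c(cand,
              vapply(graph$synonyms[[accession]] %||% list(),
                     function(s) s$text, character(1)),
              vapply(graph$definitions[[accession]] %||% list(),
                     function(d) d$text, character(1)),
              unlist(graph$annotations[[accession]] %||% list(),
                     use.names = FALSE))
  }
  cand[nzchar(cand)]
}

search_graph <- function(graph, query, options) {
  q <- tolower(query)
  hits <- character()
  for (a in sort_c(names(graph$terms))) {
    t <- graph$terms[[a]]
    if (t$obsolete && !options$include_obsolete) next
    cand <- tolower(search_candidates(graph, a, options))
    hit <- if (options$exact) any(cand == q)
    else any(grepl(q, cand, fixed = TRUE))
    if (hit) hits <- c(hits, a)
  }
  materialize(graph, hits)
}

#' @export
service_invoke.file_service <- function(service, op, args = list()) {
  switch(
    op,
    list_ontologies = lapply(sort_c(names(service$graphs)),
                             function(a) service$graphs[[a]]$metadata),
    get_ontology = {
      o <- args$ontology_accession
      if (is.null(o) || !o %in% names(service$graphs)) NULL
      else service$graphs[[o]]$metadata
    },
    search_all = {
      out <- list()
      for (a in sort_c(names(service$graphs)))
        out <- c(out, search_graph(service$graphs[[a]], args$query,
                                   args$options))
      out
    },
    search_ontology = {
      g <- fs_graph(service, args$ontology_accession)
      search_graph(g, args$query, args$options)
    },
    get_term = {
      o <- args$ontology_accession
      t <- args$term_accession
      if (is.null(o)) {
        o <- unname(service$index[t])
        if (is.na(o)) return(NULL)
      }
      if (!o %in% names(service$graphs)) return(NULL)
      service$graphs[[o]]$terms[[t]]
    },
    get_all_terms = {
      g <- fs_graph(service, args$ontology_accession)
      materialize(g, sort_c(names(g$terms)))
    },
    get_annotations = {
      g <- fs_resolve(service, args$ontology_accession, args$term_accession)
      g$annotations[[args$term_accession]] %||% list()
    },
    get_synonyms = {
      g <- fs_resolve(service, args$ontology_accession, args$term_accession)
      sort_c(unique(vapply(g$synonyms[[args$term_accession]] %||% list(),
                           function(s) s$text, character(1))))
    },
    get_definitions = {
      g <- fs_resolve(service, args$ontology_accession, args$term_accession)
      sort_c(unique(vapply(g$definitions[[args$term_accession]] %||% list(),
                           function(d) d$text, character(1))))
    },
    get_root_terms = {
      g <- fs_graph(service, args$ontology_accession)
      materialize(g, root_accessions(g))
    },
    get_children = {
      g <- fs_resolve(service, args$ontology_accession, args$term_accession)
      materialize(g, direct_children(g, args$term_accession))
    },
    get_parents = {
      g <- fs_resolve(service, args$ontology_accession, args$term_accession)
      materialize(g, direct_parents(g, args$term_accession))
    },
    get_all_children = {
      g <- fs_resolve(service, args$ontology_accession, args$term_accession)
      materialize(g, descendants(g, args$term_accession))
    },
    get_all_parents = {
      g <- fs_resolve(service, args$ontology_accession, args$term_accession)
      materialize(g, ancestors(g, args$term_accession))
    },
    get_term_path = {
      g <- fs_resolve(service, args$ontology_accession, args$term_accession)
      materialize(g, path_to_root(g, args$term_accession))
    },
    get_relations = {
      g <- fs_resolve(service, args$ontology_accession, args$term_accession)
      t <- args$term_accession
      rel <- g$relations[g$relations$subject == t, , drop = FALSE]
      out <- list()
      for (name in sort_c(unique(rel$relation))) {
        objs <- sort_c(rel$object[rel$relation == name])
        out[[name]] <- lapply(objs, function(o) g$terms[[o]] %||% o)
      }
      xr <- g$xrefs[[t]] %||% character()
      if (length(xr)) out[["xref"]] <- xr
      out
    },
    stop(sprintf("unknown operation '%s'", op))
  )
}
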