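# Shared helpers: independent traversal oracle, graph comparison views,
# stub services for decorator tests, and small conveniences.

# Independent transitive-closure oracle: boolean reachability matrix by
# repeated multiplication (no shared code with the package's work-list
# traversals). closure[i, j] is TRUE when j is an ancestor of i.
closure_oracle <- function(graph) {
  accs <- sort(names(graph$terms))
  n <- length(accs)
  A <- matrix(FALSE, n, n, dimnames = list(accs, accs))
  for (k in seq_len(nrow(graph$is_a)))
    A[graph$is_a$child[[k]], graph$is_a$parent[[k]]] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

oracle_ancestors <- function(closure, acc) sort(names(which(closure[acc, ])))
oracle_descendants <- function(closure, acc) sort(names(which(closure[, acc])))

# Full-fidelity comparison view for OBO round trips: everything write_obo
# promises to preserve, including synonym scopes.
graph_signature <- function(g) {
  accs <- sort(names(g$terms))
  list(
    ontology = g$metadata$accession,
    labels = vapply(accs, function(a) g$terms[[a]]$label, character(1)),
    obsolete = vapply(accs, function(a) g$terms[[a]]$obsolete, logical(1)),
    edges = {
      e <- g$is_a[order(g$is_a$child, g$is_a$parent), , drop = FALSE]
      rownames(e) <- NULL
      e
    },
    relations = {
      r <- g$relations[order(g$relations$subject, g$relations$relation,
                             g$relations$object), , drop = FALSE]
      rownames(r) <- NULL
      r
    },
    synonyms = lapply(setNames(accs, accs), function(a)
      sort(vapply(g$synonyms[[a]] %||% list(), function(s)
        paste(s$scope, s$text, paste(s$xrefs, collapse = ",")),
        character(1)))),
    definitions = lapply(setNames(accs, accs), function(a)
      sort(vapply(g$definitions[[a]] %||% list(), function(d)
        paste(d$text, paste(d$xrefs, collapse = ",")), character(1)))),
    xrefs = lapply(setNames(accs, accs), function(a)
      sort(g$xrefs[[a]] %||% character()))
  )
}

normalized <- function(g) ontoquery:::normalized_view(g)
`%||%` <- function(a, b) if (is.null(a)) b else a

toy_expected <- function() {
  jsonlite::fromJSON(
    system.file("extdata", "toy_expected.json", package = "ontoquery"),
    simplifyVector = TRUE)
}

term_accessions <- function(terms)
  vapply(terms, function(t) t$accession, character(1))

# A two-term cyclic graph (A is_a B, B is_a A); built by hand because the
# generator is acyclic by construction.
cyclic_graph <- function() {
  ontology_graph(
    ontology_record("CYC", format = "OBO"),
    terms = list(
      "CYC:A" = ontology_term("CYC:A", "a", "CYC"),
      "CYC:B" = ontology_term("CYC:B", "b", "CYC")),
    is_a = data.frame(child = c("CYC:A", "CYC:B"),
                      parent = c("CYC:B", "CYC:A"),
                      stringsAsFactors = FALSE))
}

# Programmable stub service with a call log, for decorator tests.
stub_service <- function(responder) {
  env <- new.env(parent = emptyenv())
  env$calls <- list()
  env$fail <- FALSE
  structure(list(responder = responder, env = env),
            class = c("stub_service", "ontology_service"))
}

service_invoke.stub_service <- function(service, op, args = list()) {
  service$env$calls <- c(service$env$calls,
                         list(list(op = op, args = args)))
  if (isTRUE(service$env$fail))
    stop(ontoquery:::onto_error("onto_service_unavailable",
                                "stub backend down"))
  service$responder(op, args)
}
registerS3method("service_invoke", "stub_service",
                 service_invoke.stub_service,
                 envir = asNamespace("ontoquery"))

stub_call_count <- function(stub) length(stub$env$calls)

# A stub that mirrors a real file service, so contract results are
# realistic while failure and call counts stay controllable.
mirror_stub <- function(inner_service) {
  stub_service(function(op, args)
    ontoquery::service_invoke(inner_service, op, args))
}

toy_service <- function() file_service(list(toy_graph()))

write_toy_obo <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "toy.obo")
  writeLines(toy_obo_text(), path)
  path
}

# All 16 contract operations evaluated against a service for one
# ontology; used to compare services (loopback equality, decorator
# transparency). Errors are folded into comparable strings.
contract_snapshot <- function(service, ontology, term_accs,
                              queries = c("cell", "synonym", "a")) {
  safely <- function(expr) tryCatch(expr, error = function(e) {
    paste("ERROR", class(e)[[1L]])
  })
  out <- list(
    ontologies = safely(list_ontologies(service)),
    record = safely(get_ontology(service, ontology)),
    absent_record = safely(get_ontology(service, "NO_SUCH_ONTOLOGY")),
    all_terms = safely(get_all_terms(service, ontology)),
    roots = safely(get_root_terms(service, ontology)),
    absent_term = safely(get_term(service, "NOPE:1", ontology))
  )
  for (q in queries) {
    for (opts in list(search_options(), search_options(exact = TRUE),
                      search_options(include_properties = TRUE),
                      search_options(include_obsolete = TRUE))) {
      key <- paste("search", q, opts$exact, opts$include_properties,
                   opts$include_obsolete)
      out[[key]] <- safely(search_all(service, q, opts))
      out[[paste(key, "onto")]] <-
        safely(search_ontology(service, ontology, q, opts))
    }
  }
  for (acc in term_accs) {
    term <- get_term(service, acc, ontology)
    out[[paste("term", acc)]] <- term
    out[[paste("index", acc)]] <- safely(get_term(service, acc))
    for (op in c("get_children", "get_parents", "get_all_children",
                 "get_all_parents", "get_term_path", "get_synonyms",
                 "get_definitions", "get_annotations", "get_relations")) {
      fn <- get(op, envir = asNamespace("ontoquery"))
      out[[paste(op, acc)]] <- safely(fn(service, term))
    }
  }
  out
}
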