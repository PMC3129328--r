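# HTTP/JSON access path. `serve()` exposes any ontology service over a
# fixed GET route table; `http_backend()` is a client implementing the
# same service contract over that dialect, so a served service and a
# remote one are interchangeable. The wire format is JSON only.

# --- wire documents ----------------------------------------------------

term_doc <- function(t) {
  list(accession = t$accession, label = t$label,
       ontologyAccession = t$ontology_accession,
       uri = t$uri, obsolete = t$obsolete)
}

doc_term <- function(d) {
  ontology_term(d$accession, d$label %||% "", d$ontologyAccession %||% "",
                uri = d$uri, obsolete = isTRUE(d$obsolete))
}

record_doc <- function(r) {
  list(accession = r$accession, name = r$name, version = r$version,
       releaseDate = if (is.null(r$release_date)) NULL
       else format(r$release_date, "%Y-%m-%d"),
       format = r$format, termCount = r$term_count)
}

doc_record <- function(d) {
  ontology_record(d$accession, d$name %||% "", d$version %||% "",
                  release_date = if (is.null(d$releaseDate)) NULL
                  else as.Date(d$releaseDate),
                  format = d$format, term_count = d$termCount %||% 0L)
}

relations_doc <- function(rel) {
  out <- list()
  for (name in names(rel)) {
    out[[name]] <- if (name == "xref") I(as.character(rel[[name]]))
    else lapply(rel[[name]], function(x)
      if (inherits(x, "ontology_term")) term_doc(x) else x)
  }
  out
}

doc_relations <- function(d) {
  out <- list()
  for (name in names(d)) {
    out[[name]] <- if (name == "xref") {
      unlist(d[[name]], use.names = FALSE) %||% character()
    } else {
      lapply(d[[name]], function(x) if (is.list(x)) doc_term(x) else x)
    }
  }
  out
}

annotations_doc <- function(ann) lapply(ann, I)

doc_annotations <- function(d)
  lapply(d, function(v) unlist(v, use.names = FALSE))

# --- server ------------------------------------------------------------

json_response <- function(body, status = 200L) {
  list(status = status,
       headers = list("Content-Type" = "application/json; charset=utf-8"),
       body = as.character(jsonlite::toJSON(
         body, auto_unbox = TRUE, null = "null", digits = NA)))
}

json_error_response <- function(status, message)
  json_response(list(error = message), status = status)

# List payloads are plain arrays; when capped at max_results the payload
# becomes {"items": [...], "truncated": true}.
list_payload <- function(docs, max_results) {
  if (length(docs) > max_results)
    list(items = docs[seq_len(max_results)], truncated = TRUE)
  else docs
}

parse_query_string <- function(qs) {
  qs <- sub("^\\?", "", qs %||% "")
  if (!nzchar(qs)) return(list())
  out <- list()
  for (pair in strsplit(qs, "&", fixed = TRUE)[[1L]]) {
    kv <- strsplit(pair, "=", fixed = TRUE)[[1L]]
    if (!length(kv)) next
    key <- utils::URLdecode(kv[[1L]])
    val <- if (length(kv) > 1L)
      utils::URLdecode(gsub("+", "%20", paste(kv[-1L], collapse = "="),
                            fixed = TRUE)) else ""
    out[[key]] <- val
  }
  out
}

flag_on <- function(x) !is.null(x) && x %in% c("1", "true", "TRUE")

route_request <- function(service, req, max_results) {
  path <- req$PATH_INFO %||% "/"
  query <- parse_query_string(req$QUERY_STRING)
  seg <- strsplit(sub("^/+", "", path), "/", fixed = TRUE)[[1L]]
  seg <- vapply(seg, utils::URLdecode, character(1), USE.NAMES = FALSE)

  term_docs <- function(terms) lapply(terms, term_doc)

  tryCatch({
    if (length(seg) == 1L && seg[[1L]] == "search") {
      q <- query$query
      if (is.null(q) || !nzchar(trimws(q)))
        return(json_error_response(400L, "empty query"))
      opts <- search_options(exact = flag_on(query$exact),
                             include_properties = flag_on(query$properties),
                             include_obsolete = flag_on(query$obsolete))
      hits <- if (!is.null(query$ontologies) && nzchar(query$ontologies)) {
        ontos <- strsplit(query$ontologies, ",", fixed = TRUE)[[1L]]
        out <- list()
        for (o in ontos)
          out <- c(out, search_ontology(service, o, q, opts))
        out
      } else {
        search_all(service, q, opts)
      }
      return(json_response(list_payload(term_docs(hits), max_results)))
    }
    if (!length(seg) || seg[[1L]] != "ontologies")
      return(json_error_response(404L, "no such route"))
    if (length(seg) == 1L)
      return(json_response(list_payload(
        lapply(list_ontologies(service), record_doc), max_results)))
    o <- seg[[2L]]
    if (length(seg) == 2L) {
      rec <- get_ontology(service, o)
      if (is.null(rec))
        return(json_error_response(404L, sprintf("unknown ontology '%s'", o)))
      return(json_response(record_doc(rec)))
    }
    if (length(seg) == 3L && seg[[3L]] == "roots")
      return(json_response(list_payload(
        term_docs(get_root_terms(service, o)), max_results)))
    if (seg[[3L]] != "terms")
      return(json_error_response(404L, "no such route"))
    if (length(seg) == 3L && is.null(query$accession))
      return(json_response(list_payload(
        term_docs(get_all_terms(service, o)), max_results)))
    if (length(seg) == 3L) seg <- c(seg, "")   # ?accession= fallback
    tacc <- if (length(seg) >= 4L && nzchar(seg[[4L]])) seg[[4L]]
            else query$accession
    if (is.null(tacc))
      return(json_error_response(404L, "no term accession"))
    term <- get_term(service, tacc, o)
    if (is.null(term))
      return(json_error_response(
        404L, sprintf("unknown term '%s' in ontology '%s'", tacc, o)))
    if (length(seg) == 4L) return(json_response(term_doc(term)))
    sub_op <- seg[[5L]]
    result <- switch(
      sub_op,
      children = list_payload(term_docs(get_children(service, term)),
                              max_results),
      parents = list_payload(term_docs(get_parents(service, term)),
                             max_results),
      ancestors = list_payload(term_docs(get_all_parents(service, term)),
                               max_results),
      descendants = list_payload(term_docs(get_all_children(service, term)),
                                 max_results),
      path = list_payload(term_docs(get_term_path(service, term)),
                          max_results),
      synonyms = I(get_synonyms(service, term)),
      definitions = I(get_definitions(service, term)),
      annotations = annotations_doc(get_annotations(service, term)),
      relations = relations_doc(get_relations(service, term)),
      return(json_error_response(404L, "no such route"))
    )
    json_response(result)
  },
  onto_term_not_found = function(e)
    json_error_response(404L, conditionMessage(e)),
  onto_ontology_not_found = function(e)
    json_error_response(404L, conditionMessage(e)),
  onto_invalid_query = function(e)
    json_error_response(400L, conditionMessage(e)),
  onto_cyclic_hierarchy = function(e)
    json_error_response(422L, conditionMessage(e)),
  error = function(e) json_error_response(500L, conditionMessage(e)))
}

#' Serve an ontology service over HTTP/JSON
#'
#' Registers a non-blocking HTTP server exposing the full operation
#' contract as GET routes: `/ontologies`, `/ontologies/{o}`,
#' `/ontologies/{o}/roots`, `/ontologies/{o}/terms`,
#' `/ontologies/{o}/terms/{t}`, `/ontologies/{o}/terms/{t}/{children|
#' parents|ancestors|descendants|path|synonyms|definitions|annotations|
#' relations}` and `/search?query=Q&exact=0|1&properties=0|1&obsolete=0|1
#' [&ontologies=A,B]`. Term accessions in paths are percent-encoded
#' (`:` as `%3A`); `?accession=` is accepted as a fallback for clients
#' that cannot path-encode. Unknown ontology/term maps to 404, an empty
#' query to 400, a cyclic hierarchy on `/path` to 422. List responses are
#' truncated at `max_results` with a `"truncated": true` marker.
#'
#' The caller must keep the R event loop serviced (e.g.
#' [run_server_loop()]) for requests to be handled.
#'
#' @param service Any `ontology_service`.
#' @param host Interface to bind.
#' @param port TCP port (must be free).
#' @param max_results Cap on list response length.
#' @return A server handle; pass to [stop_server()].
#' @export
serve <- function(service, host = "127.0.0.1", port = 8765L,
                  max_results = 10000L) {
  app <- list(call = function(req) {
    if (!identical(req$REQUEST_METHOD, "GET"))
      return(json_error_response(405L, "GET only"))
    route_request(service, req, max_results)
  })
  server <- httpuv::startServer(host, port, app)
  structure(list(server = server, host = host, port = port,
                 base_url = sprintf("http://%s:%d", host, port)),
            class = "onto_server")
}

#' Stop a running server
#' @param handle A handle returned by [serve()].
#' @return `NULL`, invisibly.
#' @export
stop_server <- function(handle) {
  httpuv::stopServer(handle$server)
  invisible(NULL)
}

#' Block and service HTTP requests forever
#'
#' @param poll_ms Poll interval in milliseconds.
#' @return Does not return; interrupt to stop.
#' @export
run_server_loop <- function(poll_ms = 100) {
  repeat httpuv::service(poll_ms)
}

#' Serve ontology files from a background R process
#'
#' Spawns a child R process that builds a [file_service()] over `inputs`
#' and serves it, then waits until the server answers. This is how a
#' "remote" repository is stood up for loopback testing and for the CLI
#' `serve` subcommand.
#'
#' @param inputs Character vector of ontology file paths.
#' @param host Interface to bind.
#' @param port Port; default picks a random free port.
#' @param max_results Cap on list response length.
#' @param timeout_seconds How long to wait for the server to come up.
#' @return Handle with the child `process` and `base_url`; pass to
#'   [stop_background_server()].
#' @export
serve_background <- function(inputs, host = "127.0.0.1", port = NULL,
                             max_results = 10000L, timeout_seconds = 30) {
  inputs <- normalizePath(inputs, mustWork = TRUE)
  if (is.null(port)) port <- httpuv::randomPort()
  px <- callr::r_bg(
    function(inputs, host, port, max_results) {
      svc <- ontoquery::file_service(inputs)
      ontoquery::serve(svc, host = host, port = port,
                       max_results = max_results)
      ontoquery::run_server_loop()
    },
    args = list(inputs = inputs, host = host, port = port,
                max_results = max_results),
    libpath = .libPaths(),
    supervise = TRUE
  )
  base_url <- sprintf("http://%s:%d", host, port)
  deadline <- Sys.time() + timeout_seconds
  repeat {
    if (!px$is_alive()) {
      err <- tryCatch(px$read_all_error(), error = function(e) "")
      stop_service_unavailable(
        paste0("background server died during startup: ", err))
    }
    ok <- tryCatch({
      h <- curl::new_handle(timeout = 2L)
      r <- curl::curl_fetch_memory(paste0(base_url, "/ontologies"), h)
      r$status_code == 200L
    }, error = function(e) FALSE)
    if (ok) break
    if (Sys.time() > deadline) {
      px$kill()
      stop_service_unavailable("background server did not come up in time")
    }
    Sys.sleep(0.1)
  }
  structure(list(process = px, base_url = base_url, host = host,
                 port = port),
            class = "onto_background_server")
}

#' Stop a background server
#' @param handle Handle from [serve_background()].
#' @return `NULL`, invisibly.
#' @export
stop_background_server <- function(handle) {
  if (handle$process$is_alive()) handle$process$kill()
  invisible(NULL)
}

# --- client ------------------------------------------------------------

#' Ontology service backed by a remote HTTP server
#'
#' Implements every contract operation by calling the routes of
#' [serve()]'s dialect and deserializing the JSON. Network-level
#' failures (refused connection, timeout, 5xx) surface as
#' service-unavailable errors, which the [cached()] decorator can absorb;
#' 404 responses map to the contract's absent/not-found semantics.
#'
#' @param base_url Server base URL, e.g. `"http://127.0.0.1:8765"`.
#' @param timeout_seconds Per-request timeout.
#' @return An object of classes `http_service`, `ontology_service`.
#' @export
http_backend <- function(base_url, timeout_seconds = 10) {
  structure(list(base_url = sub("/+$", "", base_url),
                 timeout = timeout_seconds),
            class = c("http_service", "ontology_service"))
}

http_get_json <- function(service, path, params = list()) {
  url <- paste0(service$base_url, path)
  if (length(params)) {
    qs <- paste(vapply(names(params), function(k)
      paste0(k, "=", curl::curl_escape(as.character(params[[k]]))),
      character(1)), collapse = "&")
    url <- paste0(url, "?", qs)
  }
  h <- curl::new_handle(timeout = service$timeout)
  resp <- tryCatch(curl::curl_fetch_memory(url, h),
                   error = function(e) stop_service_unavailable(
                     paste0("HTTP request failed: ", conditionMessage(e))))
  body <- rawToChar(resp$content)
  parsed <- tryCatch(jsonlite::fromJSON(body, simplifyVector = FALSE),
                     error = function(e) NULL)
  if (resp$status_code >= 200L && resp$status_code < 300L)
    return(list(ok = TRUE, status = resp$status_code, body = parsed))
  if (resp$status_code %in% c(400L, 404L, 422L))
    return(list(ok = FALSE, status = resp$status_code, body = parsed))
  stop_service_unavailable(sprintf("HTTP %d from %s", resp$status_code, url))
}

unwrap_items <- function(body) {
  if (is.list(body) && !is.null(names(body)) && "items" %in% names(body))
    body$items else body
}

http_escape_path <- function(x) curl::curl_escape(x)

#' @export
service_invoke.http_service <- function(service, op, args = list()) {
  o <- args$ontology_accession
  t <- args$term_accession
  term_path <- function(sub_op = NULL) {
    p <- sprintf("/ontologies/%s/terms/%s", http_escape_path(o),
                 http_escape_path(t))
    if (!is.null(sub_op)) p <- paste0(p, "/", sub_op)
    p
  }
  get_terms_list <- function(path, not_found) {
    r <- http_get_json(service, path)
    if (!r$ok) not_found(r)
    lapply(unwrap_items(r$body), doc_term)
  }
  nf_term <- function(r) {
    if (r$status == 422L) stop_cyclic_hierarchy(t)
    stop_term_not_found(t, o)
  }
  nf_onto <- function(r) stop_ontology_not_found(o)

  switch(
    op,
    list_ontologies = {
      r <- http_get_json(service, "/ontologies")
      if (!r$ok) stop_service_unavailable("cannot list ontologies")
      lapply(unwrap_items(r$body), doc_record)
    },
    get_ontology = {
      r <- http_get_json(service, paste0("/ontologies/",
                                         http_escape_path(o)))
      if (!r$ok) NULL else doc_record(r$body)
    },
    search_all = ,
    search_ontology = {
      opts <- args$options
      params <- list(query = args$query,
                     exact = if (opts$exact) "1" else "0",
                     properties = if (opts$include_properties) "1" else "0",
                     obsolete = if (opts$include_obsolete) "1" else "0")
      if (op == "search_ontology") params$ontologies <- o
      r <- http_get_json(service, "/search", params)
      if (!r$ok) {
        if (r$status == 400L) stop_invalid_query()
        stop_ontology_not_found(o)
      }
      lapply(unwrap_items(r$body), doc_term)
    },
    get_term = {
      if (is.null(o)) {
        for (rec in service_invoke(service, "list_ontologies")) {
          hit <- service_invoke(service, "get_term",
                                list(ontology_accession = rec$accession,
                                     term_accession = t))
          if (!is.null(hit)) return(hit)
        }
        return(NULL)
      }
      r <- http_get_json(service, sprintf("/ontologies/%s/terms/%s",
                                          http_escape_path(o),
                                          http_escape_path(t)))
      if (!r$ok) NULL else doc_term(r$body)
    },
    get_all_terms = get_terms_list(
      sprintf("/ontologies/%s/terms", http_escape_path(o)), nf_onto),
    get_root_terms = get_terms_list(
      sprintf("/ontologies/%s/roots", http_escape_path(o)), nf_onto),
    get_children = get_terms_list(term_path("children"), nf_term),
    get_parents = get_terms_list(term_path("parents"), nf_term),
    get_all_children = get_terms_list(term_path("descendants"), nf_term),
    get_all_parents = get_terms_list(term_path("ancestors"), nf_term),
    get_term_path = get_terms_list(term_path("path"), nf_term),
    get_synonyms = {
      r <- http_get_json(service, term_path("synonyms"))
      if (!r$ok) nf_term(r)
      unlist(r$body, use.names = FALSE) %||% character()
    },
    get_definitions = {
      r <- http_get_json(service, term_path("definitions"))
      if (!r$ok) nf_term(r)
      unlist(r$body, use.names = FALSE) %||% character()
    },
    get_annotations = {
      r <- http_get_json(service, term_path("annotations"))
      if (!r$ok) nf_term(r)
      doc_annotations(r$body)
    },
    get_relations = {
      r <- http_get_json(service, term_path("relations"))
      if (!r$ok) nf_term(r)
      doc_relations(r$body)
    },
    stop(sprintf("unknown operation '%s'", op))
  )
}
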