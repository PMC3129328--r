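# Service decorators: each wraps any ontology service and preserves the
# operation contract while adding behaviour — caching with stale
# fallback, federation over several sources, priority subsetting, and
# accession-namespace translation. Decorators compose in any order.

# Contract-level errors are answers about the data, not backend
# failures; decorators must not treat them as outages.
is_contract_error <- function(e) {
  inherits(e, c("onto_term_not_found", "onto_ontology_not_found",
                "onto_cyclic_hierarchy", "onto_invalid_query"))
}

#' Deterministic cache key for a service call
#'
#' Operation name plus the canonicalized (JSON-serialized) arguments.
#' Equal calls yield equal keys; within one operation, distinct canonical
#' arguments yield distinct keys.
#'
#' @param op Operation name.
#' @param args Named list of canonical arguments.
#' @return A single string.
#' @export
cache_key <- function(op, args = list()) {
  canonicalize <- function(x) {
    if (is.function(x) || is.environment(x))
      stop(onto_error("onto_key_error",
                      "cannot serialize arguments for cache key"))
    if (is.list(x)) lapply(unclass(x), canonicalize) else x
  }
  json <- tryCatch(
    jsonlite::toJSON(canonicalize(args), auto_unbox = TRUE, null = "null",
                     digits = NA),
    error = function(e) stop(onto_error(
      "onto_key_error",
      paste0("cannot serialize arguments for cache key: ",
             conditionMessage(e)))))
  paste0(op, "|", as.character(json))
}

#' Caching decorator with stale-result fallback
#'
#' Adds two caching layers to every request. Each call first consults a
#' TTL layer (default expiry 24 hours); on a miss the call is passed to
#' the wrapped service, and a success is stored in both the TTL layer and
#' an eternal layer. If the wrapped service fails, the eternal layer is
#' consulted, so results stay available while a backend is temporarily
#' down; with both layers empty the failure propagates.
#'
#' @param inner The wrapped `ontology_service`.
#' @param ttl_seconds Expiry of the first layer, in seconds; default one
#'   day.
#' @param clock Time source returning seconds as a number; injectable so
#'   expiry is testable. Defaults to wall-clock time.
#' @return An `ontology_service`.
#' @export
cached <- function(inner, ttl_seconds = 86400,
                   clock = function() as.numeric(Sys.time())) {
  stopifnot(ttl_seconds > 0, is.function(clock))
  structure(
    list(inner = inner, ttl_seconds = ttl_seconds, clock = clock,
         ttl_cache = new.env(parent = emptyenv()),
         eternal_cache = new.env(parent = emptyenv())),
    class = c("cached_service", "ontology_service"))
}

#' @export
service_invoke.cached_service <- function(service, op, args = list()) {
  key <- cache_key(op, args)
  now <- service$clock()
  hit <- get0(key, envir = service$ttl_cache, inherits = FALSE)
  if (!is.null(hit) && (now - hit$stored_at) < service$ttl_seconds)
    return(hit$value)
  result <- tryCatch(
    list(ok = TRUE, value = service_invoke(service$inner, op, args)),
    error = function(e) list(ok = FALSE, condition = e))
  if (result$ok) {
    entry <- list(value = result$value, stored_at = now)
    assign(key, entry, envir = service$ttl_cache)
    assign(key, entry, envir = service$eternal_cache)
    return(result$value)
  }
  eternal <- get0(key, envir = service$eternal_cache, inherits = FALSE)
  if (!is.null(eternal)) return(eternal$value)
  stop(result$condition)
}

#' Federating decorator over several services
#'
#' Presents an ordered list of services as one. Searches and ontology
#' listings fan out to every backend and results are concatenated in
#' service-declaration order, so output is deterministic regardless of
#' how backends are scheduled. Single-valued lookups return the first
#' non-absent answer in service order (replicas of an ontology are never
#' merged: one version wins). A backend that fails is skipped with a
#' warning — dropout redundancy — unless `strict = TRUE`, in which case
#' the failure propagates.
#'
#' @param services Non-empty list of `ontology_service` objects, in
#'   priority order.
#' @param workers Accepted for interface compatibility (must be >= 1);
#'   requests are executed sequentially in service order.
#' @param strict If `TRUE`, backend failures propagate instead of being
#'   skipped.
#' @return An `ontology_service`.
#' @export
composite <- function(services, workers = 1L, strict = FALSE) {
  stopifnot(is.list(services), length(services) >= 1L, workers >= 1L)
  structure(list(services = services, workers = as.integer(workers),
                 strict = isTRUE(strict)),
            class = c("composite_service", "ontology_service"))
}

#' @export
service_invoke.composite_service <- function(service, op, args = list()) {
  fan_out <- op %in% c("search_all", "search_ontology", "list_ontologies")
  results <- list()
  any_ok <- FALSE
  last_contract <- NULL
  failures <- list()
  for (s in service$services) {
    r <- tryCatch(list(ok = TRUE, value = service_invoke(s, op, args)),
                  error = function(e) list(ok = FALSE, condition = e))
    if (!r$ok) {
      e <- r$condition
      if (is_contract_error(e)) {
        if (inherits(e, "onto_cyclic_hierarchy") ||
            inherits(e, "onto_invalid_query")) stop(e)
        last_contract <- e          # not-found here; maybe found elsewhere
      } else if (service$strict) {
        stop(e)
      } else {
        failures <- c(failures, list(e))
        warning(sprintf("composite: backend failed for %s (%s); skipping",
                        op, conditionMessage(e)), call. = FALSE)
      }
      next
    }
    any_ok <- TRUE
    if (fan_out) {
      results <- c(results, r$value)
    } else {
      # first non-absent answer wins
      if (!is.null(r$value)) return(r$value)
    }
  }
  if (fan_out) {
    if (!any_ok && !is.null(last_contract)) stop(last_contract)
    if (!any_ok && length(failures))
      stop_service_unavailable(sprintf(
        "composite: all %d backend(s) failed for %s", length(failures), op))
    return(results)
  }
  if (any_ok) return(NULL)          # every backend answered "absent"
  if (!is.null(last_contract)) stop(last_contract)
  if (length(failures))
    stop_service_unavailable(sprintf(
      "composite: all %d backend(s) failed for %s", length(failures), op))
  NULL
}

#' Priority-subsetting decorator
#'
#' Truncates every search result to terms from an initial list of
#' ontologies and ranks them in the order the ontologies were specified
#' (ties keep the wrapped service's order). Non-search operations pass
#' through unchanged.
#'
#' @param inner The wrapped `ontology_service`.
#' @param priority Non-empty ordered character vector of ontology
#'   accessions.
#' @return An `ontology_service`.
#' @export
sorted_subset <- function(inner, priority) {
  stopifnot(is.character(priority), length(priority) >= 1L)
  structure(list(inner = inner, priority = priority),
            class = c("sorted_subset_service", "ontology_service"))
}

#' @export
service_invoke.sorted_subset_service <- function(service, op, args = list()) {
  out <- service_invoke(service$inner, op, args)
  if (!op %in% c("search_all", "search_ontology")) return(out)
  ranks <- vapply(out, function(t)
    match(t$ontology_accession, service$priority), integer(1))
  keep <- which(!is.na(ranks))
  out[keep][order(ranks[keep], method = "radix")]   # stable sort
}

#' Accession-translation decorator
#'
#' Rewrites incoming term and ontology accessions between identifier
#' namespaces before delegating, bridging e.g. OWL-style `NCBITaxon_1`
#' and OBO-style `NCBITaxon:1`. Each identifier is tested against the
#' mappings' match patterns in order and the first match's rewrite rules
#' are applied; non-matching identifiers pass through unchanged. Results
#' are returned exactly as the wrapped service produced them (no reverse
#' translation).
#'
#' @param inner The wrapped `ontology_service`.
#' @param mappings List of [ontology_id_mapping()] rules.
#' @return An `ontology_service`.
#' @export
translated <- function(inner, mappings = list()) {
  if (inherits(mappings, "ontology_id_mapping")) mappings <- list(mappings)
  stopifnot(all(vapply(mappings, inherits, logical(1),
                       "ontology_id_mapping")))
  structure(list(inner = inner, mappings = mappings),
            class = c("translated_service", "ontology_service"))
}

translate_id <- function(x, mappings, which) {
  if (is.null(x)) return(NULL)
  for (m in mappings) {
    if (grepl(m$match_pattern, x)) {
      rw <- m[[which]]
      if (!is.null(rw)) {
        out <- gsub(rw[[1L]], rw[[2L]], x)
        if (!nzchar(out))
          stop_translation_error(sprintf(
            "rewrite of '%s' produced an empty accession", x))
        return(out)
      }
      return(x)
    }
  }
  x
}

#' @export
service_invoke.translated_service <- function(service, op, args = list()) {
  if (!is.null(args$term_accession))
    args$term_accession <- translate_id(args$term_accession,
                                        service$mappings, "term_rewrite")
  if (!is.null(args$ontology_accession))
    args$ontology_accession <- translate_id(args$ontology_accession,
                                            service$mappings,
                                            "ontology_rewrite")
  service_invoke(service$inner, op, args)
}

#' Load accession-translation rules from a config file
#'
#' The file is a JSON array; each entry has a `match` pattern and
#' optional `term` and `ontology` rewrite pairs
#' (`{"match": "...", "term": ["pat", "rep"], "ontology": ["pat", "rep"]}`).
#'
#' @param path Path to the JSON file.
#' @return List of [ontology_id_mapping()] rules.
#' @export
read_id_mappings <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(entry) {
    ontology_id_mapping(
      match_pattern = entry$match,
      term_rewrite = if (!is.null(entry$term))
        unlist(entry$term, use.names = FALSE),
      ontology_rewrite = if (!is.null(entry$ontology))
        unlist(entry$ontology, use.names = FALSE))
  })
}
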