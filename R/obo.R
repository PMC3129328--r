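# OBO 1.2 flat-file reader and writer. The dialect accepted is OBO 1.2
# with the 1.4 synonym syntax; obsolete pre-1.2 scoped synonym tags
# (exact_synonym etc.) are accepted and normalized. Trailing "! comment"
# text is stripped before value parsing, except inside quoted strings.

OBO_LEGACY_SYNONYM_TAGS <- c(exact_synonym = "EXACT", broad_synonym = "BROAD",
                             narrow_synonym = "NARROW",
                             related_synonym = "RELATED")

# --- low-level lexing --------------------------------------------------

# Strip an unquoted, unescaped "! ..." trailing comment.
strip_obo_comment <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  in_quote <- FALSE
  esc <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (esc) { esc <- FALSE; next }
    if (ch == "\\") { esc <- TRUE; next }
    if (ch == "\"") in_quote <- !in_quote
    else if (ch == "!" && !in_quote)
      return(sub("[ \t]+$", "", substr(s, 1L, i - 1L)))
  }
  s
}

# Resolve OBO backslash escapes (\: \" \\ \n and, generically, \x -> x).
unescape_obo <- function(s) {
  if (!grepl("\\", s, fixed = TRUE)) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  out <- character(length(chars))
  j <- 0L
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "\\" && i < n) {
      nxt <- chars[[i + 1L]]
      j <- j + 1L
      out[[j]] <- if (nxt == "n") "\n" else nxt
      i <- i + 2L
    } else {
      j <- j + 1L
      out[[j]] <- ch
      i <- i + 1L
    }
  }
  paste(out[seq_len(j)], collapse = "")
}

escape_obo <- function(s, quoted = FALSE) {
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  if (quoted) {
    s <- gsub("\"", "\\\"", s, fixed = TRUE)
  } else {
    s <- gsub("!", "\\!", s, fixed = TRUE)
    s <- gsub("{", "\\{", s, fixed = TRUE)
  }
  s
}

# Extract a leading quoted string; returns list(text, rest) or NULL when
# the quote is unbalanced.
take_quoted <- function(s) {
  s <- sub("^[ \t]+", "", s)
  if (!startsWith(s, "\"")) return(NULL)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  esc <- FALSE
  for (i in seq_along(chars)[-1L]) {
    ch <- chars[[i]]
    if (esc) { esc <- FALSE; next }
    if (ch == "\\") { esc <- TRUE; next }
    if (ch == "\"") {
      return(list(text = unescape_obo(substr(s, 2L, i - 1L)),
                  rest = sub("^[ \t]+", "", substr(s, i + 1L, nchar(s)))))
    }
  }
  NULL
}

# Parse a bracketed xref list "[A:1, B:2 \"desc\"]"; trailing quoted
# descriptions are dropped, commas inside quotes respected.
parse_xref_list <- function(s) {
  s <- sub("^[ \t]+", "", s)
  if (!startsWith(s, "[")) return(character())
  inner <- sub("^\\[", "", sub("\\][^]]*$", "", s))
  if (!nzchar(trimws(inner))) return(character())
  parts <- character()
  buf <- ""
  in_quote <- FALSE
  esc <- FALSE
  for (ch in strsplit(inner, "", fixed = TRUE)[[1L]]) {
    if (esc) { buf <- paste0(buf, ch); esc <- FALSE; next }
    if (ch == "\\") { buf <- paste0(buf, ch); esc <- TRUE; next }
    if (ch == "\"") in_quote <- !in_quote
    if (ch == "," && !in_quote) { parts <- c(parts, buf); buf <- "" }
    else buf <- paste0(buf, ch)
  }
  parts <- c(parts, buf)
  parts <- vapply(parts, function(p) {
    p <- trimws(p)
    p <- sub("[ \t]+\".*$", "", p)   # drop trailing description
    unescape_obo(p)
  }, character(1), USE.NAMES = FALSE)
  parts[nzchar(parts)]
}

# --- tag-value parsers -------------------------------------------------

#' Parse the value of an OBO synonym tag
#'
#' Grammar: a quoted synonym text, an optional scope token (`EXACT`,
#' `BROAD`, `NARROW`, `RELATED`), an optional synonym-type name, and an
#' optional bracketed cross-reference list. A missing scope yields
#' `UNSPECIFIED`.
#'
#' @param raw The tag value, e.g. `"\"neuroglia\" BROAD [FMA:0]"`.
#' @return A [synonym_value()].
#' @export
parse_synonym_tag <- function(raw) {
  q <- take_quoted(raw)
  if (is.null(q))
    stop_malformed(sprintf("unbalanced quote in synonym tag: %s", raw))
  rest <- q$rest
  scope <- "UNSPECIFIED"
  tok <- sub("^([^ \t\\[]+).*$", "\\1", rest)
  if (nzchar(tok) && tok %in% c("EXACT", "BROAD", "NARROW", "RELATED")) {
    scope <- tok
    rest <- sub("^[^ \t\\[]+[ \t]*", "", rest)
  }
  synonym_value(q$text, scope = scope, xrefs = parse_xref_list(rest))
}

#' Parse the value of an OBO def tag
#'
#' As [parse_synonym_tag()] but without a scope token: a quoted definition
#' text followed by an optional bracketed cross-reference list.
#'
#' @param raw The tag value.
#' @return A [definition_value()].
#' @export
parse_def_tag <- function(raw) {
  q <- take_quoted(raw)
  if (is.null(q))
    stop_malformed(sprintf("unbalanced quote in def tag: %s", raw))
  definition_value(q$text, xrefs = parse_xref_list(q$rest))
}

# --- document parser ---------------------------------------------------

obo_input_lines <- function(x) {
  if (inherits(x, "connection")) return(readLines(x, warn = FALSE))
  if (is.character(x) && length(x) == 1L && !grepl("\n", x, fixed = TRUE) &&
      file.exists(x))
    return(readLines(x, warn = FALSE))
  if (is.character(x) && length(x) == 1L)
    return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  if (is.character(x)) return(x)
  stop("parse_obo input must be a path, a connection, or character text")
}

#' Parse an OBO 1.2/1.4 document into an ontology graph
#'
#' Header tags populate the [ontology_record()] (`ontology` uppercased is
#' the default ontology accession; `data-version` the version; `date` the
#' release date). Each `[Term]` stanza becomes one term: `name` is the
#' label, `synonym`/`def` tags are parsed into scoped synonym and
#' definition values (their raw forms kept in the annotation set), `is_a`
#' feeds the hierarchy, `relationship: REL TARGET` the typed relation
#' edges, `xref` the cross-references, and `is_obsolete: true` the
#' obsolete flag. `[Typedef]` stanzas and unknown tags are preserved
#' verbatim as annotations.
#'
#' @param x A file path, connection, or the document text itself (a single
#'   string with embedded newlines, or a character vector of lines).
#' @param ontology_accession Optional override for the ontology accession;
#'   wins over the header's `ontology` tag.
#' @return An [ontology_graph()].
#' @export
parse_obo <- function(x, ontology_accession = NULL) {
  lines <- obo_input_lines(x)

  header <- list()
  terms <- list(); annotations <- list(); synonyms <- list()
  definitions <- list(); xrefs <- list()
  edge_child <- character(); edge_parent <- character()
  rel_subject <- character(); rel_name <- character(); rel_object <- character()
  typedefs <- list()

  stanza_type <- NA_character_   # NA = header
  stanza_lines <- integer()
  stanza_tags <- list()          # list of c(tag, value) pairs
  stanza_start <- 0L

  flush_stanza <- function() {
    if (is.na(stanza_type)) return()
    if (stanza_type == "Term") {
      ids <- vapply(stanza_tags, function(p) p[[1L]] == "id", logical(1))
      if (!any(ids))
        stop_malformed("[Term] stanza has no id tag", line = stanza_start)
      id <- unescape_obo(stanza_tags[[which(ids)[1L]]][[2L]])
      if (!nzchar(id))
        stop_malformed("[Term] stanza has empty id", line = stanza_start)
      label <- ""
      obsolete <- FALSE
      ann <- list()
      syns <- list(); defs <- list(); xr <- character()
      for (p in stanza_tags) {
        tag <- p[[1L]]; val <- p[[2L]]
        if (tag == "id") next
        if (tag == "name") { label <- unescape_obo(val); next }
        if (tag == "is_obsolete") {
          obsolete <- identical(tolower(trimws(val)), "true")
          next
        }
        if (tag == "is_a") {
          edge_child <<- c(edge_child, id)
          edge_parent <<- c(edge_parent, unescape_obo(trimws(val)))
          next
        }
        if (tag == "relationship") {
          parts <- strsplit(trimws(val), "[ \t]+")[[1L]]
          if (length(parts) >= 2L) {
            rel_subject <<- c(rel_subject, id)
            rel_name <<- c(rel_name, parts[[1L]])
            rel_object <<- c(rel_object, unescape_obo(parts[[2L]]))
          }
          next
        }
        if (tag == "xref") {
          xr <- c(xr, unescape_obo(sub("[ \t]+\".*$", "", trimws(val))))
          ann[["xref"]] <- c(ann[["xref"]], val)
          next
        }
        if (tag == "synonym" || tag %in% names(OBO_LEGACY_SYNONYM_TAGS)) {
          sv <- parse_synonym_tag(val)
          if (tag != "synonym" && sv$scope == "UNSPECIFIED")
            sv$scope <- OBO_LEGACY_SYNONYM_TAGS[[tag]]
          syns <- c(syns, list(sv))
          ann[["synonym"]] <- c(ann[["synonym"]], val)
          next
        }
        if (tag == "def") {
          defs <- c(defs, list(parse_def_tag(val)))
          ann[["def"]] <- c(ann[["def"]], val)
          next
        }
        # alt_id and every unknown tag: preserved verbatim
        ann[[tag]] <- c(ann[[tag]], val)
      }
      terms[[id]] <<- ontology_term(id, label, "", obsolete = obsolete)
      if (length(ann)) annotations[[id]] <<- ann
      if (length(syns)) synonyms[[id]] <<- syns
      if (length(defs)) definitions[[id]] <<- defs
      if (length(xr)) xrefs[[id]] <<- xr
    } else {
      raw <- vapply(stanza_tags, function(p)
        paste0(p[[1L]], ": ", p[[2L]]), character(1))
      typedefs[[length(typedefs) + 1L]] <<-
        list(type = stanza_type, tags = raw)
    }
  }

  for (i in seq_along(lines)) {
    line <- strip_obo_comment(lines[[i]])
    if (grepl("^\\[.*\\]\\s*$", line)) {
      flush_stanza()
      stanza_type <- sub("^\\[(.*)\\]\\s*$", "\\1", line)
      stanza_tags <- list()
      stanza_start <- i
      next
    }
    if (!nzchar(trimws(line))) next
    m <- regexpr(":", line, fixed = TRUE)
    if (m < 1L) next
    tag <- trimws(substr(line, 1L, m - 1L))
    val <- sub("^[ \t]+", "", substr(line, m + 1L, nchar(line)))
    if (is.na(stanza_type)) header[[tag]] <- c(header[[tag]], val)
    else stanza_tags[[length(stanza_tags) + 1L]] <- list(tag, val)
  }
  flush_stanza()

  if (is.null(header[["format-version"]]))
    warning("OBO document has no format-version header", call. = FALSE)

  acc <- ontology_accession %||%
    (if (!is.null(header[["ontology"]])) toupper(header[["ontology"]][[1L]])
     else "UNKNOWN")
  release_date <- NULL
  if (!is.null(header[["date"]])) {
    d <- try(as.Date(header[["date"]][[1L]], format = "%d:%m:%Y %H:%M"),
             silent = TRUE)
    if (!inherits(d, "try-error") && !is.na(d)) release_date <- d
  }
  record <- ontology_record(
    accession = acc,
    name = (header[["ontology"]] %||% acc)[[1L]],
    version = (header[["data-version"]] %||% "")[[1L]],
    release_date = release_date,
    format = "OBO",
    term_count = length(terms)
  )

  # stamp owning ontology onto each term
  terms <- lapply(terms, function(t) { t$ontology_accession <- acc; t })

  extra_header <- header[setdiff(names(header),
                                 c("format-version", "ontology",
                                   "data-version", "date"))]
  graph_ann <- list()
  if (length(extra_header)) graph_ann$header <- extra_header
  if (!is.null(header[["format-version"]]))
    graph_ann$format_version <- header[["format-version"]][[1L]]
  if (length(typedefs)) graph_ann$typedefs <- typedefs

  is_a <- unique(data.frame(child = edge_child, parent = edge_parent,
                            stringsAsFactors = FALSE))
  rel <- unique(data.frame(subject = rel_subject, relation = rel_name,
                           object = rel_object, stringsAsFactors = FALSE))

  # edges must point at known terms; drop dangling references with a warning
  keep <- is_a$child %in% names(terms) & is_a$parent %in% names(terms)
  if (any(!keep))
    warning(sprintf("dropping %d is_a edge(s) with unknown endpoints",
                    sum(!keep)), call. = FALSE)
  ontology_graph(record, terms = terms, annotations = annotations,
                 synonyms = synonyms, definitions = definitions,
                 is_a = is_a[keep, , drop = FALSE],
                 relations = rel, xrefs = xrefs,
                 graph_annotations = graph_ann)
}

# --- writer ------------------------------------------------------------

format_synonym_tag <- function(sv) {
  scope <- if (sv$scope == "UNSPECIFIED") "" else paste0(" ", sv$scope)
  sprintf("\"%s\"%s [%s]", escape_obo(sv$text, quoted = TRUE), scope,
          paste(vapply(sv$xrefs, escape_obo, character(1), quoted = FALSE),
                collapse = ", "))
}

format_def_tag <- function(dv) {
  sprintf("\"%s\" [%s]", escape_obo(dv$text, quoted = TRUE),
          paste(vapply(dv$xrefs, escape_obo, character(1), quoted = FALSE),
                collapse = ", "))
}

#' Write an ontology graph as an OBO 1.2 document
#'
#' Terms are emitted in lexicographic accession order; parsing the output
#' with [parse_obo()] reproduces the graph (terms, labels, edges, scoped
#' synonyms, definitions, xrefs, obsolete flags).
#'
#' @param graph An [ontology_graph()].
#' @param path File path or writable connection.
#' @return `path`, invisibly.
#' @export
write_obo <- function(graph, path) {
  out <- c("format-version: 1.2",
           paste0("ontology: ", tolower(graph$metadata$accession)))
  if (nzchar(graph$metadata$version))
    out <- c(out, paste0("data-version: ", graph$metadata$version))
  if (!is.null(graph$metadata$release_date))
    out <- c(out, paste0("date: ",
                         format(graph$metadata$release_date, "%d:%m:%Y 00:00")))

  known <- c("synonym", "def", "xref")
  for (acc in sort_c(names(graph$terms))) {
    t <- graph$terms[[acc]]
    stanza <- c("", "[Term]", paste0("id: ", escape_obo(acc)))
    if (nzchar(t$label))
      stanza <- c(stanza, paste0("name: ", escape_obo(t$label)))
    ann <- graph$annotations[[acc]] %||% list()
    for (a in ann[["alt_id"]] %||% character())
      stanza <- c(stanza, paste0("alt_id: ", a))
    for (dv in graph$definitions[[acc]] %||% list())
      stanza <- c(stanza, paste0("def: ", format_def_tag(dv)))
    for (sv in graph$synonyms[[acc]] %||% list())
      stanza <- c(stanza, paste0("synonym: ", format_synonym_tag(sv)))
    for (x in graph$xrefs[[acc]] %||% character())
      stanza <- c(stanza, paste0("xref: ", escape_obo(x)))
    parents <- sort_c(graph$is_a$parent[graph$is_a$child == acc])
    for (p in parents)
      stanza <- c(stanza, paste0("is_a: ", escape_obo(p)))
    rel <- graph$relations[graph$relations$subject == acc, , drop = FALSE]
    if (nrow(rel)) {
      rel <- rel[order(rel$relation, rel$object, method = "radix"), ,
                 drop = FALSE]
      stanza <- c(stanza, sprintf("relationship: %s %s", rel$relation,
                                  vapply(rel$object, escape_obo,
                                         character(1))))
    }
    extra <- setdiff(names(ann), c(known, "alt_id"))
    for (tag in sort_c(extra))
      for (v in ann[[tag]]) stanza <- c(stanza, paste0(tag, ": ", v))
    if (t$obsolete) stanza <- c(stanza, "is_obsolete: true")
    out <- c(out, stanza)
  }

  for (td in graph$graph_annotations$typedefs %||% list())
    out <- c(out, "", paste0("[", td$type, "]"), td$tags)

  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
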