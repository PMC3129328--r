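# Deterministic test ontologies: a small hand-specified anatomy/cell
# ontology ("TOY") that every contract example is enumerated against, and
# a seeded random generator producing acyclic graphs of configurable
# shape. Neither requires any download.

#' The TOY fixture ontology as OBO text
#'
#' @return A single string holding an OBO 1.2 document.
#' @export
toy_obo_text <- function() {
  paste(c(
    "format-version: 1.2",
    "ontology: toy",
    "",
    "[Term]",
    "id: TOY:0000001",
    "name: anatomical entity",
    "",
    "[Term]",
    "id: TOY:0000002",
    "name: cell",
    "synonym: \"cellule\" EXACT []",
    "is_a: TOY:0000001",
    "",
    "[Term]",
    "id: TOY:0000003",
    "name: neuron",
    "def: \"An electrically excitable cell.\" [PMID:0000001]",
    "is_a: TOY:0000002",
    "",
    "[Term]",
    "id: TOY:0000004",
    "name: glial cell",
    "synonym: \"neuroglia\" BROAD [FMA:0]",
    "is_a: TOY:0000002",
    "",
    "[Term]",
    "id: TOY:0000005",
    "name: organelle",
    "is_a: TOY:0000001",
    "",
    "[Term]",
    "id: TOY:0000006",
    "name: mitochondrion",
    "xref: GO:0005739",
    "is_a: TOY:0000005",
    "",
    "[Term]",
    "id: TOY:0000007",
    "name: obsolete membrane",
    "is_obsolete: true"
  ), collapse = "\n")
}

#' The TOY fixture ontology
#'
#' Seven terms under ontology accession `"TOY"`: a root
#' ("anatomical entity"), a two-level cell branch (cell, neuron, glial
#' cell) with one scoped synonym each on cell and glial cell and a
#' definition on neuron, an organelle branch (organelle, mitochondrion
#' with a GO cross-reference), and one obsolete term.
#'
#' @return An [ontology_graph()] with 7 terms, 5 `is_a` edges, 1 obsolete
#'   term.
#' @export
toy_graph <- function() parse_obo(toy_obo_text())

GENERATOR_WORDS <- c(
  "cell", "membrane", "nucleus", "organelle", "tissue", "neuron", "glia",
  "vesicle", "receptor", "kinase", "ligand", "channel", "cortex", "lobe",
  "artery", "vein", "muscle", "fibre", "gland", "duct", "epithelium",
  "stroma", "plasma", "axon", "dendrite", "synapse", "ganglion", "node",
  "follicle", "villus", "crypt", "lumen", "matrix", "capsule", "septum",
  "sinus", "papilla", "plexus", "tract", "fossa")

#' Parameters for the random ontology generator
#'
#' @param n_terms Number of terms (>= 1).
#' @param n_roots Number of root terms (1 <= `n_roots` <= `n_terms`).
#' @param max_children Soft cap on direct children per term.
#' @param synonym_rate,definition_rate,obsolete_rate,multi_parent_rate
#'   Probabilities in `[0, 1]` that a term receives a synonym, a
#'   definition, the obsolete flag, or a second parent.
#' @param xref_rate Probability of a cross-reference on a term.
#' @param seed RNG seed; the same parameters always produce the same
#'   graph.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n_terms, n_roots = 1L, max_children = 4L,
                             synonym_rate = 0.3, definition_rate = 0.3,
                             obsolete_rate = 0.05, multi_parent_rate = 0.1,
                             xref_rate = 0.2, seed = 1L) {
  rates <- c(synonym_rate, definition_rate, obsolete_rate,
             multi_parent_rate, xref_rate)
  if (n_terms < 1L || n_roots < 1L || n_roots > n_terms || max_children < 1L ||
      any(rates < 0) || any(rates > 1))
    stop(onto_error("onto_parameter_error", "invalid generator parameters"))
  structure(list(n_terms = as.integer(n_terms), n_roots = as.integer(n_roots),
                 max_children = as.integer(max_children),
                 synonym_rate = synonym_rate,
                 definition_rate = definition_rate,
                 obsolete_rate = obsolete_rate,
                 multi_parent_rate = multi_parent_rate,
                 xref_rate = xref_rate, seed = as.integer(seed)),
            class = "generator_params")
}

# run code under a private RNG stream, restoring the caller's stream
with_private_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a random acyclic ontology graph
#'
#' Terms are created in accession order (`RND:0000001`, ...) and every
#' parent is drawn only from already-created terms, so the result is
#' acyclic by construction. Labels come from a fixed word list; synonym,
#' definition, obsolescence, multi-parent and cross-reference features are
#' sampled at the configured rates. Deterministic for a given seed.
#'
#' @param params A [generator_params()].
#' @param accession Ontology accession of the generated graph; override
#'   it when loading several generated ontologies side by side.
#' @return An [ontology_graph()] with ontology accession `accession`.
#' @export
random_graph <- function(params, accession = "RND") {
  stopifnot(inherits(params, "generator_params"))
  with_private_seed(params$seed, {
    n <- params$n_terms
    accs <- sprintf("RND:%07d", seq_len(n))
    terms <- list(); synonyms <- list(); definitions <- list()
    annotations <- list(); xrefs <- list()
    child <- character(); parent <- character()
    n_children <- integer(n)   # direct-child counts, for max_children

    scopes <- c("EXACT", "BROAD", "NARROW", "RELATED", "UNSPECIFIED")
    for (i in seq_len(n)) {
      acc <- accs[[i]]
      label <- paste(sample(GENERATOR_WORDS, 2L), collapse = " ")
      obsolete <- stats::runif(1) < params$obsolete_rate
      terms[[acc]] <- ontology_term(acc, label, accession,
                                    obsolete = obsolete)
      ann <- list()
      if (i > params$n_roots) {
        open <- which(n_children[seq_len(i - 1L)] < params$max_children)
        if (!length(open)) open <- seq_len(i - 1L)
        p1 <- if (length(open) == 1L) open else sample(open, 1L)
        child <- c(child, acc); parent <- c(parent, accs[[p1]])
        n_children[[p1]] <- n_children[[p1]] + 1L
        if (i > 2L && stats::runif(1) < params$multi_parent_rate) {
          others <- setdiff(seq_len(i - 1L), p1)
          if (length(others)) {
            p2 <- if (length(others) == 1L) others else sample(others, 1L)
            child <- c(child, acc); parent <- c(parent, accs[[p2]])
            n_children[[p2]] <- n_children[[p2]] + 1L
          }
        }
      }
      if (stats::runif(1) < params$synonym_rate) {
        sv <- synonym_value(paste(sample(GENERATOR_WORDS, 1L), "synonym"),
                            scope = sample(scopes, 1L))
        synonyms[[acc]] <- list(sv)
        ann$synonym <- format_synonym_tag(sv)
      }
      if (stats::runif(1) < params$definition_rate) {
        dv <- definition_value(
          sprintf("A %s related to %s.", sample(GENERATOR_WORDS, 1L),
                  sample(GENERATOR_WORDS, 1L)),
          xrefs = sprintf("PMID:%07d", sample.int(9999999L, 1L)))
        definitions[[acc]] <- list(dv)
        ann$def <- format_def_tag(dv)
      }
      if (stats::runif(1) < params$xref_rate) {
        xr <- sprintf("XR:%05d", sample.int(99999L, 1L))
        xrefs[[acc]] <- xr
        ann$xref <- xr
      }
      if (length(ann)) annotations[[acc]] <- ann
    }
    record <- ontology_record(accession, name = "random fixture ontology",
                              version = sprintf("seed-%d", params$seed),
                              format = "OBO", term_count = n)
    ontology_graph(record, terms = terms, annotations = annotations,
                   synonyms = synonyms, definitions = definitions,
                   is_a = unique(data.frame(child = child, parent = parent,
                                            stringsAsFactors = FALSE)),
                   xrefs = xrefs)
  })
}

#' Write a graph in all three supported file dialects
#'
#' Emits the graph as an OBO file, a SKOS-dialect OWL file, and an
#' OBO-in-OWL-dialect OWL file.
#'
#' @param graph An [ontology_graph()].
#' @param directory Writable directory.
#' @return Named character vector of the three paths (`obo`, `skos_owl`,
#'   `oboinowl_owl`).
#' @export
write_fixture_set <- function(graph, directory) {
  if (!dir.exists(directory))
    stop(sprintf("not a directory: %s", directory))
  stem <- tolower(graph$metadata$accession)
  paths <- c(
    obo = file.path(directory, paste0(stem, ".obo")),
    skos_owl = file.path(directory, paste0(stem, ".skos.owl")),
    oboinowl_owl = file.path(directory, paste0(stem, ".oboinowl.owl")))
  write_obo(graph, paths[["obo"]])
  write_owl(graph, paths[["skos_owl"]], dialect = "SKOS")
  write_owl(graph, paths[["oboinowl_owl"]], dialect = "OBOINOWL")
  paths
}
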