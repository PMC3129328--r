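test_that("ontology listing and record lookup behave as specified", {
  svc <- toy_service()
  recs <- list_ontologies(svc)
  expect_length(recs, 1L)
  expect_identical(recs[[1L]]$accession, "TOY")
  expect_identical(recs[[1L]]$term_count, 7L)

  expect_identical(get_ontology(svc, "TOY"), recs[[1L]])
  expect_null(get_ontology(svc, "NOPE"))
  expect_null(get_ontology(svc, "toy"))   # accessions are case-sensitive

  empty <- file_service(list())
  expect_identical(list_ontologies(empty), list())

  two <- file_service(list(toy_graph(),
                           random_graph(generator_params(10, seed = 3))))
  expect_identical(vapply(list_ontologies(two), function(r) r$accession,
                          character(1)),
                   c("RND", "TOY"))
})

test_that("the TOY search table holds, wholesale", {
  svc <- toy_service()
  searches <- toy_expected()$searches
  for (i in seq_len(nrow(searches))) {
    row <- searches[i, ]
    hits <- search_all(svc, row$query, search_options(
      exact = row$exact, include_properties = row$properties,
      include_obsolete = row$obsolete))
    expect_identical(term_accessions(hits),
                     as.character(row$expect[[1L]]),
                     info = sprintf("query '%s' exact=%s props=%s obs=%s",
                                    row$query, row$exact, row$properties,
                                    row$obsolete))
  }
  expect_error(search_all(svc, "   "), class = "onto_invalid_query")
})

test_that("search_ontology equals the filtered global search", {
  svc <- file_service(list(toy_graph(),
                           random_graph(generator_params(60, seed = 11))))
  expect_identical(
    term_accessions(search_ontology(svc, "TOY", "organelle",
                                    search_options(exact = TRUE))),
    "TOY:0000005")
  expect_error(search_ontology(svc, "NOPE", "x"),
               class = "onto_ontology_not_found")

  for (q in c("cell", "synonym", "ne", "a")) {
    for (opts in list(search_options(), search_options(exact = TRUE),
                      search_options(include_properties = TRUE))) {
      all_hits <- search_all(svc, q, opts)
      for (o in c("TOY", "RND")) {
        filtered <- Filter(function(t) t$ontology_accession == o, all_hits)
        expect_identical(search_ontology(svc, o, q, opts),
                         unname(filtered), info = paste(q, o))
      }
    }
  }
})

test_that("exact matches are a subset of substring matches", {
  svc <- file_service(list(toy_graph(),
                           random_graph(generator_params(80, seed = 5))))
  set.seed(17)
  corpus <- c(ontoquery:::GENERATOR_WORDS, "cell", "organelle", "synonym",
              "xyzzy")
  for (i in 1:100) {
    q <- sample(corpus, 1L)
    props <- sample(c(TRUE, FALSE), 1L)
    exact <- search_all(svc, q, search_options(exact = TRUE,
                                               include_properties = props))
    loose <- search_all(svc, q, search_options(exact = FALSE,
                                               include_properties = props))
    loose_keys <- vapply(loose, ontoquery:::term_key, character(1))
    for (t in exact)
      expect_true(ontoquery:::term_key(t) %in% loose_keys, info = q)
  }
})

test_that("obsolete terms are hidden from search unless requested, but retrievable", {
  svc <- toy_service()
  expect_identical(search_all(svc, "obsolete membrane"), list())
  hits <- search_all(svc, "obsolete membrane",
                     search_options(include_obsolete = TRUE))
  expect_identical(term_accessions(hits), "TOY:0000007")
  term <- get_term(svc, "TOY:0000007", "TOY")
  expect_true(term$obsolete)
  # obsolete terms appear, flagged, in full listings
  expect_true("TOY:0000007" %in% term_accessions(get_all_terms(svc, "TOY")))
})

test_that("term lookup is exact, case-sensitive, and indexable without an ontology", {
  svc <- toy_service()
  expect_identical(get_term(svc, "TOY:0000006", "TOY")$label,
                   "mitochondrion")
  expect_null(get_term(svc, "GO:0043227", "TOY"))
  expect_null(get_term(svc, "toy:0000006", "TOY"))
  expect_null(get_term(svc, "TOY:0000006", "NOPE"))
  expect_identical(get_term(svc, "TOY:0000006"),
                   get_term(svc, "TOY:0000006", "TOY"))
  expect_null(get_term(svc, "TOY:9999999"))
})

test_that("the cross-ontology index keeps the first ontology on collision", {
  g1 <- random_graph(generator_params(5, seed = 1), accession = "AAA")
  g2 <- random_graph(generator_params(5, seed = 2), accession = "BBB")
  w <- capture_warnings(svc <- file_service(list(g1, g2)))
  expect_true(all(grepl("collision", w)))
  expect_length(w, 5L)   # one per shared term accession
  hit <- get_term(svc, "RND:0000001")
  expect_identical(hit$ontology_accession, "AAA")
  # the two-argument form still reaches the second ontology
  expect_identical(get_term(svc, "RND:0000001", "BBB")$ontology_accession,
                   "BBB")
})

test_that("annotation access exposes raw values that projections strip", {
  svc <- toy_service()
  t4 <- get_term(svc, "TOY:0000004", "TOY")
  ann <- get_annotations(svc, t4)
  expect_identical(ann$synonym, "\"neuroglia\" BROAD [FMA:0]")
  expect_identical(get_synonyms(svc, t4), "neuroglia")

  t3 <- get_term(svc, "TOY:0000003", "TOY")
  expect_identical(get_definitions(svc, t3),
                   "An electrically excitable cell.")
  expect_match(get_annotations(svc, t3)$def, "PMID:0000001", fixed = TRUE)

  t1 <- get_term(svc, "TOY:0000001", "TOY")
  expect_identical(get_annotations(svc, t1), list())
  expect_identical(get_synonyms(svc, t1), character())
  expect_identical(get_definitions(svc, t1), character())

  t6 <- get_term(svc, "TOY:0000006", "TOY")
  expect_identical(get_annotations(svc, t6)$xref, "GO:0005739")
  expect_identical(get_relations(svc, t6), list(xref = "GO:0005739"))

  ghost <- ontology_term("TOY:9999999", "", "TOY")
  expect_error(get_annotations(svc, ghost), class = "onto_term_not_found")
})

test_that("synonym and definition projections are contained in raw annotations", {
  g <- random_graph(generator_params(60, synonym_rate = 0.6,
                                     definition_rate = 0.6, seed = 13))
  svc <- file_service(list(g))
  for (term in get_all_terms(svc, "RND")) {
    ann_blob <- paste(unlist(get_annotations(svc, term)), collapse = "\n")
    for (s in get_synonyms(svc, term))
      expect_true(grepl(s, ann_blob, fixed = TRUE))
    for (d in get_definitions(svc, term))
      expect_true(grepl(d, ann_blob, fixed = TRUE))
  }
})

test_that("hierarchy wrappers materialize full terms in graph order", {
  svc <- toy_service()
  roots <- get_root_terms(svc, "TOY")
  expect_identical(term_accessions(roots), "TOY:0000001")
  expect_identical(roots[[1L]]$label, "anatomical entity")

  t6 <- get_term(svc, "TOY:0000006", "TOY")
  expect_identical(term_accessions(get_term_path(svc, t6)),
                   c("TOY:0000001", "TOY:0000005", "TOY:0000006"))
  t4 <- get_term(svc, "TOY:0000004", "TOY")
  expect_identical(term_accessions(get_all_parents(svc, t4)),
                   c("TOY:0000001", "TOY:0000002"))
  t2 <- get_term(svc, "TOY:0000002", "TOY")
  expect_identical(term_accessions(get_children(svc, t2)),
                   c("TOY:0000003", "TOY:0000004"))
  expect_identical(term_accessions(get_parents(svc, t2)), "TOY:0000001")
  t1 <- get_term(svc, "TOY:0000001", "TOY")
  expect_identical(term_accessions(get_all_children(svc, t1)),
                   c("TOY:0000002", "TOY:0000003", "TOY:0000004",
                     "TOY:0000005", "TOY:0000006"))
  # every returned term carries the owning ontology accession
  expect_true(all(vapply(get_all_children(svc, t1), function(t)
    t$ontology_accession == "TOY", logical(1))))
})

test_that("typed relations resolve targets to terms where possible", {
  doc <- paste(c(
    "format-version: 1.2",
    "ontology: rel",
    "",
    "[Term]",
    "id: REL:1",
    "name: whole",
    "",
    "[Term]",
    "id: REL:2",
    "name: part",
    "relationship: part_of REL:1",
    "xref: EXT:77"
  ), collapse = "\n")
  svc <- file_service(list(parse_obo(doc)))
  rel <- get_relations(svc, get_term(svc, "REL:2", "REL"))
  expect_named(rel, c("part_of", "xref"))
  expect_s3_class(rel$part_of[[1L]], "ontology_term")
  expect_identical(rel$part_of[[1L]]$accession, "REL:1")
  expect_identical(rel$xref, "EXT:77")
})

test_that("repeated identical calls return identical results", {
  svc <- toy_service()
  expect_identical(search_all(svc, "cell"), search_all(svc, "cell"))
  t <- get_term(svc, "TOY:0000002", "TOY")
  expect_identical(get_all_children(svc, t), get_all_children(svc, t))
  expect_identical(get_annotations(svc, t), get_annotations(svc, t))
})
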