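test_that("cache keys are deterministic and distinguish operations and options", {
  k1 <- cache_key("search_all", list(query = "a",
                                     options = search_options()))
  k2 <- cache_key("search_all", list(query = "a",
                                     options = search_options()))
  expect_identical(k1, k2)
  k3 <- cache_key("search_all", list(query = "a",
                                     options = search_options(exact = TRUE)))
  expect_false(identical(k1, k3))
  k4 <- cache_key("search_ontology",
                  list(ontology_accession = "O", query = "a",
                       options = search_options()))
  expect_false(identical(k1, k4))
  expect_error(cache_key("op", list(f = function() NULL)),
               class = "onto_key_error")
})

test_that("a warm cache survives backend death; a cold one propagates", {
  stub <- mirror_stub(toy_service())
  cs <- cached(stub, ttl_seconds = 10, clock = function() 0)

  before <- search_all(cs, "cell")
  term <- get_term(cs, "TOY:0000002", "TOY")
  syn_before <- get_synonyms(cs, term)

  stub$env$fail <- TRUE
  expect_identical(search_all(cs, "cell"), before)
  expect_identical(get_synonyms(cs, term), syn_before)
  # never-cached call with a dead backend: failure propagates
  expect_error(search_all(cs, "never asked before"),
               class = "onto_service_unavailable")
})

test_that("TTL expiry re-queries the backend; the eternal layer outlives it", {
  stub <- mirror_stub(toy_service())
  now <- new.env(); now$t <- 0
  cs <- cached(stub, ttl_seconds = 100, clock = function() now$t)

  search_all(cs, "cell")
  n1 <- stub_call_count(stub)
  search_all(cs, "cell")                    # TTL hit: no new call
  expect_identical(stub_call_count(stub), n1)

  now$t <- 101                              # expire the TTL layer
  search_all(cs, "cell")
  expect_identical(stub_call_count(stub), n1 + 1L)

  now$t <- 300
  stub$env$fail <- TRUE                     # expired TTL + dead backend:
  expect_identical(term_accessions(search_all(cs, "cell")),
                   c("TOY:0000002", "TOY:0000004"))  # eternal layer serves
})

test_that("composite concatenates searches in service order and skips dead backends", {
  toy <- toy_service()
  rnd <- file_service(list(random_graph(generator_params(
    30, synonym_rate = 1, seed = 4))))
  comp <- composite(list(toy, rnd))

  hits <- search_all(comp, "cell", search_options(include_properties = TRUE))
  ontos <- vapply(hits, function(t) t$ontology_accession, character(1))
  expect_identical(unique(ontos), c("TOY", "RND"))   # first service first
  per_backend <- c(search_all(toy, "cell", search_options(include_properties = TRUE)),
                   search_all(rnd, "cell", search_options(include_properties = TRUE)))
  expect_identical(hits, per_backend)

  # singleton composite is transparent
  single <- composite(list(toy))
  t <- get_term(single, "TOY:0000003", "TOY")
  expect_identical(t, get_term(toy, "TOY:0000003", "TOY"))
  expect_identical(search_all(single, "cell"), search_all(toy, "cell"))
  expect_identical(get_term_path(single, t), get_term_path(toy, t))

  # one backend down: results equal the healthy rest, with a warning
  dead <- stub_service(function(op, args) stop("boom"))
  dead$env$fail <- TRUE
  mixed <- composite(list(dead, toy))
  expect_warning(got <- search_all(mixed, "cell"), "skipping")
  expect_identical(got, search_all(toy, "cell"))
  expect_warning(rec <- get_ontology(mixed, "TOY"))
  expect_identical(rec, get_ontology(toy, "TOY"))

  # strict mode propagates instead
  strict <- composite(list(dead, toy), strict = TRUE)
  expect_error(search_all(strict, "cell"),
               class = "onto_service_unavailable")

  # everything down on a lookup: aggregated failure
  all_dead <- composite(list(dead))
  expect_warning(
    expect_error(get_term(all_dead, "TOY:0000001", "TOY"),
                 class = "onto_service_unavailable"))
})

test_that("single-valued lookups return the first non-absent answer", {
  g1 <- random_graph(generator_params(5, seed = 1), accession = "AAA")
  g2 <- random_graph(generator_params(5, seed = 2), accession = "BBB")
  comp <- composite(list(file_service(list(g1)), file_service(list(g2))))
  # both backends hold RND:0000001; the first service's version wins
  expect_identical(get_term(comp, "RND:0000001", "AAA")$ontology_accession,
                   "AAA")
  expect_identical(get_term(comp, "RND:0000001")$ontology_accession, "AAA")
  # an ontology known only to the second backend is still reachable
  expect_identical(get_ontology(comp, "BBB")$accession, "BBB")
  expect_identical(
    term_accessions(get_all_terms(comp, "BBB")),
    term_accessions(get_all_terms(file_service(list(g2)), "BBB")))
  # unknown everywhere: not-found error surfaces
  expect_error(get_all_terms(comp, "NOPE"),
               class = "onto_ontology_not_found")
  expect_null(get_term(comp, "NOPE:1", "AAA"))
})

test_that("sorted_subset filters to the priority list and ranks by it", {
  toy <- toy_service()
  rnd <- file_service(list(random_graph(generator_params(
    30, synonym_rate = 1, seed = 4))))
  comp <- composite(list(toy, rnd))
  opts <- search_options(include_properties = TRUE)

  ranked <- sorted_subset(comp, c("RND", "TOY"))
  hits <- search_all(ranked, "cell", opts)
  ontos <- vapply(hits, function(t) t$ontology_accession, character(1))
  expect_identical(unique(ontos), c("RND", "TOY"))
  # stable within each ontology: same relative order as the inner service
  inner_hits <- search_all(comp, "cell", opts)
  for (o in c("RND", "TOY"))
    expect_identical(Filter(function(t) t$ontology_accession == o, hits),
                     Filter(function(t) t$ontology_accession == o,
                            inner_hits))

  # full-coverage priority in inner order is a no-op
  expect_identical(search_all(sorted_subset(comp, c("TOY", "RND")),
                              "cell", opts),
                   inner_hits)
  # priority naming an absent ontology truncates to nothing
  expect_identical(search_all(sorted_subset(comp, "ZZZ"), "cell", opts),
                   list())
  # non-search operations pass through untouched
  t <- get_term(ranked, "TOY:0000006", "TOY")
  expect_identical(get_term_path(ranked, t), get_term_path(comp, t))
})

test_that("translated rewrites matching accessions before delegation", {
  toy <- toy_service()
  underscore_to_colon <- ontology_id_mapping(
    "^NCBITaxon_\\d+$", term_rewrite = c("_", ":"))

  # the canonical OWL/OBO bridge: NCBITaxon_1 -> NCBITaxon:1
  tax <- parse_obo(c("format-version: 1.2", "ontology: ncbitaxon",
                     "[Term]", "id: NCBITaxon:1", "name: root"))
  tax_svc <- translated(file_service(list(tax)),
                        list(underscore_to_colon))
  hit <- get_term(tax_svc, "NCBITaxon_1", "NCBITAXON")
  expect_identical(hit$accession, "NCBITaxon:1")
  expect_identical(hit$label, "root")

  # empty mapping list: identity
  id <- translated(toy, list())
  expect_identical(get_term(id, "TOY:0000002", "TOY"),
                   get_term(toy, "TOY:0000002", "TOY"))
  # non-matching accessions pass through unchanged
  thru <- translated(toy, list(underscore_to_colon))
  expect_identical(get_term(thru, "TOY:0000002", "TOY"),
                   get_term(toy, "TOY:0000002", "TOY"))
  # a rewrite that erases the accession is an error
  eraser <- translated(toy, list(ontology_id_mapping(
    "^TOY:\\d+$", term_rewrite = c("^TOY:\\d+$", ""))))
  expect_error(get_term(eraser, "TOY:0000002", "TOY"),
               class = "onto_translation_error")
  # mappings also rewrite ontology accessions
  onto_map <- translated(toy, list(ontology_id_mapping(
    "^1000$", ontology_rewrite = c("^1000$", "TOY"))))
  expect_identical(get_ontology(onto_map, "1000")$accession, "TOY")
})

test_that("decorators are transparent when configured neutrally, even stacked", {
  toy <- toy_service()
  neutral <- cached(
    composite(list(translated(sorted_subset(toy, "TOY"), list()))),
    clock = function() 0)
  snap_direct <- contract_snapshot(toy, "TOY", names(toy_graph()$terms))
  snap_wrapped <- contract_snapshot(neutral, "TOY",
                                    names(toy_graph()$terms))
  expect_identical(snap_wrapped, snap_direct)
})
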