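test_that("accessions derive from URI fragments, then path segments", {
  expect_identical(accession_from_uri("http://sig.uw.edu/fma#Anatomical_entity"),
                   "Anatomical_entity")
  expect_identical(accession_from_uri("http://purl.org/obo/NCBITaxon_1"),
                   "NCBITaxon_1")
  expect_identical(accession_from_uri("plain"), "plain")
  expect_identical(accession_from_uri("http://x.org/a/b#C:1"), "C:1")
})

test_that("label resolution follows user property, rdfs:label, skos:prefLabel, fragment", {
  rdfs_label <- "http://www.w3.org/2000/01/rdf-schema#label"
  pref <- "http://www.w3.org/2004/02/skos/core#prefLabel"
  custom <- "http://example.org/myLabel"

  expect_identical(resolve_label(list(), "http://x.org/fma#Heart"), "Heart")
  expect_identical(
    resolve_label(setNames(list("x", "y"), c(custom, rdfs_label)),
                  "http://x.org/fma#Heart",
                  label_policy(custom)),
    "x")
  expect_identical(
    resolve_label(setNames(list("A", "B"), c(rdfs_label, pref)),
                  "http://x.org/t#T"),
    "A")
  expect_identical(resolve_label(setNames(list("z"), pref),
                                 "http://x.org/t#T"), "z")
  # empty values are skipped, not returned
  expect_identical(resolve_label(setNames(list(""), rdfs_label),
                                 "http://x.org/t#Frag"), "Frag")
})

test_that("both OWL dialects round-trip the TOY graph on the normalized view", {
  toy <- toy_graph()
  for (dialect in c("SKOS", "OBOINOWL")) {
    path <- withr::local_tempfile(fileext = ".owl")
    write_owl(toy, path, dialect = dialect)
    reread <- parse_owl(path)
    expect_identical(normalized(reread), normalized(toy), info = dialect)
    expect_identical(reread$metadata$format, "OWL")
  }
})

test_that("OBO-in-OWL synonym scopes survive the OBOINOWL dialect", {
  toy <- toy_graph()
  path <- withr::local_tempfile(fileext = ".owl")
  write_owl(toy, path, dialect = "OBOINOWL")
  g <- parse_owl(path)
  sv <- g$synonyms[["TOY:0000004"]][[1L]]
  expect_identical(sv$text, "neuroglia")
  expect_identical(sv$scope, "BROAD")
  # raw values stay reachable through the annotation set, keyed by URI
  ann <- g$annotations[["TOY:0000004"]]
  expect_true(
    "http://www.geneontology.org/formats/oboInOwl#hasBroadSynonym" %in%
      names(ann))
})

test_that("deprecated classes and ObsoleteClass subtrees are flagged obsolete", {
  doc <- paste(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '  xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '  xmlns:owl="http://www.w3.org/2002/07/owl#">',
    '  <owl:Ontology rdf:about="http://x.org/dep"/>',
    '  <owl:Class rdf:about="http://x.org/dep#ObsoleteClass"/>',
    '  <owl:Class rdf:about="http://x.org/dep#D:1">',
    '    <rdfs:label>gone</rdfs:label>',
    '    <owl:deprecated>true</owl:deprecated>',
    '  </owl:Class>',
    '  <owl:Class rdf:about="http://x.org/dep#D:2">',
    '    <rdfs:label>bucketed</rdfs:label>',
    '    <rdfs:subClassOf rdf:resource="http://x.org/dep#ObsoleteClass"/>',
    '  </owl:Class>',
    '  <owl:Class rdf:about="http://x.org/dep#D:3">',
    '    <rdfs:label>alive</rdfs:label>',
    '  </owl:Class>',
    '</rdf:RDF>'), collapse = "\n")
  g <- parse_owl(doc)
  expect_false("ObsoleteClass" %in% names(g$terms))
  expect_true(g$terms[["D:1"]]$obsolete)
  expect_true(g$terms[["D:2"]]$obsolete)
  expect_false(g$terms[["D:3"]]$obsolete)
  # edges into the obsolete bucket never enter the hierarchy
  expect_identical(nrow(g$is_a), 0L)
})

test_that("accession collisions keep the first class in document order", {
  doc <- paste(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '  xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '  xmlns:owl="http://www.w3.org/2002/07/owl#">',
    '  <owl:Ontology rdf:about="http://x.org/coll"/>',
    '  <owl:Class rdf:about="http://first.org/ns#Shared">',
    '    <rdfs:label>first</rdfs:label>',
    '  </owl:Class>',
    '  <owl:Class rdf:about="http://second.org/other#Shared">',
    '    <rdfs:label>second</rdfs:label>',
    '  </owl:Class>',
    '</rdf:RDF>'), collapse = "\n")
  expect_warning(g <- parse_owl(doc), "collision")
  expect_identical(g$terms[["Shared"]]$label, "first")
  expect_identical(g$terms[["Shared"]]$uri, "http://first.org/ns#Shared")
})

test_that("restriction superclasses are ignored and bad XML is a format error", {
  doc <- paste(c(
    '<?xml version="1.0"?>',
    '<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
    '  xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"',
    '  xmlns:owl="http://www.w3.org/2002/07/owl#">',
    '  <owl:Ontology rdf:about="http://x.org/r"/>',
    '  <owl:Class rdf:about="http://x.org/r#A">',
    '    <rdfs:subClassOf>',
    '      <owl:Restriction>',
    '        <owl:onProperty rdf:resource="http://x.org/r#part_of"/>',
    '      </owl:Restriction>',
    '    </rdfs:subClassOf>',
    '  </owl:Class>',
    '</rdf:RDF>'), collapse = "\n")
  g <- parse_owl(doc)
  expect_identical(nrow(g$is_a), 0L)
  expect_length(g$terms, 1L)

  expect_error(suppressWarnings(parse_owl("<rdf:RDF")),
               class = "onto_malformed")
})

test_that("OBO and both OWL dialects of one graph agree on the normalized view", {
  for (seed in c(7, 21)) {
    g <- random_graph(generator_params(80, multi_parent_rate = 0.15,
                                       seed = seed))
    dir <- withr::local_tempdir()
    paths <- write_fixture_set(g, dir)
    from_obo <- parse_obo(paths[["obo"]])
    from_skos <- parse_owl(paths[["skos_owl"]])
    from_oio <- parse_owl(paths[["oboinowl_owl"]])
    expect_identical(normalized(from_obo), normalized(g))
    expect_identical(normalized(from_skos), normalized(g))
    expect_identical(normalized(from_oio), normalized(g))
  }
})
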