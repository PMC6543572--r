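# OWL and JSON serialization.

owl_class_names <- function(doc, ns) {
  nodes <- xml2::xml_find_all(doc, "//owl:Class")
  sub(ns, "", xml2::xml_attr(nodes, "rdf:about"), fixed = TRUE)
}

test_that("an empty dSON serializes to exactly the base vocabulary", {
  d <- generate_all(dson("Empty"))
  doc <- to_owl(d)
  classes <- xml2::xml_find_all(doc, "//owl:Class")
  props <- xml2::xml_find_all(doc, "//owl:AnnotationProperty")
  expect_equal(length(classes), 9L)
  expect_equal(length(props), 13L)
  expect_setequal(owl_class_names(doc, d$namespace), sonq:::SON_CLASSES)
  expect_setequal(sub(d$namespace, "", xml2::xml_attr(props, "rdf:about"),
                      fixed = TRUE),
                  sonq:::SON_PROPERTIES)
})

test_that("every emitted document carries the 9/13 vocabulary plus domain classes", {
  for (seed in c(3, 11)) {
    d <- generate_all(random_dson(seed))
    doc <- to_owl(d)
    names_ <- owl_class_names(doc, d$namespace)
    expect_true(all(sonq:::SON_CLASSES %in% names_))
    expect_equal(sum(names_ %in% sonq:::SON_CLASSES), 9L)
    expect_equal(length(xml2::xml_find_all(doc, "//owl:AnnotationProperty")),
                 13L)
    n_domain <- length(sonq:::all_concepts(d)) + length(d$composite_terms) +
      length(d$multiple_queries)
    expect_equal(length(names_), 9L + n_domain)
  }
})

test_that("the Niti composite class carries the printed query annotation", {
  d <- generate_all(build_niti_dson(), generation_options("en"))
  doc <- to_owl(d)
  classes <- xml2::xml_find_all(doc, "//owl:Class")
  hit <- which(xml2::xml_attr(classes, "rdf:about") ==
                 paste0(d$namespace, "Unexpected__Complication"))
  expect_length(hit, 1L)
  node <- classes[[hit]]
  q <- xml2::xml_text(xml2::xml_find_first(node, ".//son:query"))
  expect_equal(q, paste0("(unexpected OR unforeseeable OR unknown) AND ",
                         "(complication OR failure OR incident)"))
})

test_that("to_owl refuses dSONs with ungenerated queries", {
  expect_error(to_owl(build_niti_dson()), "ungenerated")
})

test_that("from_owl inverts to_owl on the Niti fixture and an empty dSON", {
  d <- generate_all(build_niti_dson(), generation_options("en"))
  expect_dson_equal(from_owl(to_owl(d)), d)

  e <- generate_all(dson("Empty"))
  back <- from_owl(to_owl(e))
  expect_equal(length(back$facets), 0L)
  expect_equal(back$name, "Empty")
})

test_that("from_owl requires the SON vocabulary and skips orphan classes", {
  expect_error(from_owl('<?xml version="1.0"?>
    <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
             xmlns:owl="http://www.w3.org/2002/07/owl#">
      <owl:Class rdf:about="http://x.org/ns#Thing"/>
    </rdf:RDF>'), "missing SON vocabulary")

  d <- generate_all(build_niti_dson(), generation_options("en"))
  doc <- to_owl(d)
  xml2::xml_add_child(doc, "owl:Class",
                      "rdf:about" = paste0(d$namespace, "Orphan_Class"))
  warns <- character(0)
  back <- withCallingHandlers(
    from_owl(doc),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_equal(sum(grepl("Orphan_Class", warns)), 1L)
  expect_dson_equal(back, d)
})

test_that("OWL round-trips preserve randomized generated dSONs", {
  for (seed in 1:25) {
    d <- generate_all(random_dson(seed + 100))
    expect_dson_equal(from_owl(to_owl(d)), d)
  }
})

test_that("Turtle input is accepted on read", {
  ttl <- '
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix : <http://example.org/dson/T#> .
@prefix meta: <http://son-generator.org/meta#> .
:T a owl:Ontology ; meta:dson_name "Turtled" .
:Search_Concept a owl:Class .
:Standard_Concept a owl:Class ; rdfs:subClassOf :Search_Concept .
:Negated_Concept a owl:Class ; rdfs:subClassOf :Search_Concept .
:Composite_Term a owl:Class .
:Multiple_Concept_Query a owl:Class .
:Stent a owl:Class ; rdfs:subClassOf :Standard_Concept ;
  meta:facet "Device" ;
  :simple_term "stent"@en ;
  :query "(stent)"@en .
'
  d <- from_owl(ttl)
  expect_equal(d$name, "Turtled")
  expect_equal(length(d$facets), 1L)
  expect_equal(d$facets[[1]]$name, "Device")
  st <- resolve_concept(d, "Stent")
  expect_equal(st$simple_terms[[1]]$text, "stent")
  expect_equal(st$query$en, "(stent)")
})

test_that("JSON export has fixed shape and validates against the schema", {
  e <- generate_all(dson("Empty"))
  j <- jsonlite::parse_json(to_json(e))
  expect_equal(names(j), c("name", "facets", "negated_concepts",
                           "multiple_concept_queries"))
  expect_equal(length(j$facets), 0L)
  expect_equal(validate_json(to_json(e)), character(0))

  d <- generate_all(build_niti_dson(), generation_options("en"))
  js <- to_json(d)
  expect_equal(validate_json(js), character(0))
  parsed <- jsonlite::parse_json(js)
  material <- parsed$facets[[1]]
  niti <- material$concepts[[1]]
  expect_equal(niti$name, "Nitinol")
  expect_equal(length(niti$simple_terms$en), 3L)
  expect_equal(names(niti),
               c("name", "type", "simple_terms", "query", "children"))
})

test_that("the schema validator actually rejects malformed documents", {
  expect_gt(length(validate_json('{"name": "x"}')), 0L)
  expect_gt(length(validate_json(
    '{"name": 5, "facets": [], "negated_concepts": [],
      "multiple_concept_queries": []}')), 0L)
})

test_that("JSON via OWL equals JSON computed directly", {
  for (seed in c(5, 17, 23)) {
    d <- generate_all(random_dson(seed + 200))
    expect_identical(to_json(from_owl(to_owl(d))), to_json(d))
  }
})

test_that("external label ontologies import as facets", {
  ttl <- '
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix : <http://x.org/onto#> .
:B a owl:Class .
:A a owl:Class ; rdfs:subClassOf :B ; rdfs:label "alpha"@en .
'
  f <- import_external_ontology(ttl, "Imported")
  expect_equal(f$name, "Imported")
  expect_equal(vapply(f$concepts, `[[`, character(1), "name"), c("B", "A"))
  expect_equal(f$concepts[[2]]$parent, "B")
  expect_equal(f$concepts[[2]]$simple_terms[[1]]$text, "alpha")
  # label-less class falls back to its local name
  expect_equal(f$concepts[[1]]$simple_terms[[1]]$text, "B")
})

test_that("diamond superclasses attach to the first parent with a warning", {
  ttl <- '
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix : <http://x.org/onto#> .
:B a owl:Class .
:C a owl:Class .
:A a owl:Class ; rdfs:subClassOf :B , :C ; rdfs:label "alpha"@en .
'
  warns <- character(0)
  f <- withCallingHandlers(
    import_external_ontology(ttl, "Dia"),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  expect_equal(sum(grepl("multiple superclasses", warns)), 1L)
  a <- Filter(function(co) co$name == "A", f$concepts)[[1]]
  expect_equal(a$parent, "B")
})

test_that("importing an ontology without classes is an error", {
  expect_error(
    import_external_ontology('<?xml version="1.0"?>
      <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"/>',
      "Empty"),
    "empty ontology")
})

test_that("single class with no label becomes a concept named by itself", {
  xml <- '<?xml version="1.0"?>
    <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
             xmlns:owl="http://www.w3.org/2002/07/owl#">
      <owl:Class rdf:about="http://x.org/onto#Stent"/>
    </rdf:RDF>'
  f <- import_external_ontology(xml, "Devices")
  expect_equal(f$concepts[[1]]$name, "Stent")
  expect_equal(f$concepts[[1]]$simple_terms[[1]]$text, "Stent")
})
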