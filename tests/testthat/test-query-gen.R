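# Query-string generation.

test_that("term rendering handles words, phrases and boosts", {
  expect_equal(render_term(son_term("incident", boost = 5)), "incident^5")
  expect_equal(render_term(son_term("endoscopic clipping system")),
               '"endoscopic clipping system"')
  expect_equal(render_term(son_term("clip")), "clip")
  expect_equal(render_term(son_term("nickel titanium", boost = 2)),
               '"nickel titanium"^2')
  expect_equal(render_term(son_term("clip*")), "clip*")
})

test_that("composite terms AND-connect the OR-linked part terms", {
  d <- build_niti_dson()
  expect_equal(
    generate_composite_term(d$composite_terms[[1]], d, "en"),
    "(unexpected OR unforeseeable OR unknown) AND (complication OR failure OR incident)")
})

test_that("NEAR and MODE settings rewrite the composite joiner and wrapper", {
  d <- build_niti_dson()
  ct <- d$composite_terms[[1]]
  ct$near <- "S"
  expect_equal(
    generate_composite_term(ct, d, "en"),
    "(unexpected OR unforeseeable OR unknown) NEAR/S (complication OR failure OR incident)")
  ct$near <- "5"
  expect_match(generate_composite_term(ct, d, "en"), " NEAR/5 ", fixed = TRUE)
  ct$near <- NULL
  ct$mode <- "E"
  expect_equal(
    generate_composite_term(ct, d, "en"),
    "MODE/E ((unexpected OR unforeseeable OR unknown) AND (complication OR failure OR incident))")
})

test_that("minimal one-term composite renders as (a) AND (b)", {
  d <- dson("Mini", facets = list(son_facet("F", list(
    son_concept("A", simple_terms = list(son_term("a"))),
    son_concept("B", simple_terms = list(son_term("b")))))),
    composite_terms = list(son_composite(concept = "A", part1 = "A",
                                         part2 = "B")))
  expect_equal(generate_composite_term(d$composite_terms[[1]], d, "en"),
               "(a) AND (b)")
  expect_error(generate_composite_term(d$composite_terms[[1]], d, "de"),
               "no simple terms in language 'de'")
})

test_that("single concept queries OR-join simple and composite terms", {
  d <- generate_all(build_niti_dson(), generation_options("en"))
  expect_equal(resolve_concept(d, "Nitinol")$query$en,
               '(Nitinol OR "Nickel Titanium" OR NiTi)')
  expect_equal(resolve_concept(d, "No_Preclinical")$query$en,
               "NOT (animal OR study OR preclinical)")
  expect_equal(
    resolve_concept(d, "Unexpected_Complication")$query$en,
    "(((unexpected OR unforeseeable OR unknown) AND (complication OR failure OR incident)))")
})

test_that("negated concepts inherit terms of their excluded concepts", {
  d <- build_niti_dson()
  d$negated_concepts[[1]]$excluded_concept_refs <- "Stent"
  q <- generate_single_concept_query(d$negated_concepts[[1]], d, "en")
  expect_equal(q, "NOT (animal OR study OR preclinical OR stent)")
})

test_that("multiple concept queries compose standard and negated parts", {
  d <- generate_all(build_niti_dson(), generation_options("en"))
  expect_equal(
    d$multiple_queries[[1]]$query$en,
    paste0("(((unexpected OR unforeseeable OR unknown) AND ",
           "(complication OR failure OR incident))) AND ",
           '(Nitinol OR "Nickel Titanium" OR NiTi) AND ',
           '("endoscopic clipping system") AND ',
           "NOT (animal OR study OR preclinical)"))

  mini <- dson("Mini", facets = list(son_facet("F", list(
    son_concept("A", simple_terms = list(son_term("a"))),
    son_concept("B", simple_terms = list(son_term("b")))))),
    multiple_queries = list(son_multi_query("Q", c("A", "B"))))
  g <- generate_all(mini, generation_options("en"))
  expect_equal(g$multiple_queries[[1]]$query$en, "(a) AND (b)")

  mini$multiple_queries[[1]]$near <- "3"
  g2 <- generate_all(mini, generation_options("en"))
  expect_equal(g2$multiple_queries[[1]]$query$en, "(a) NEAR/3 (b)")
})

test_that("NEAR joins only standard parts; negated concepts attach with AND", {
  d <- build_niti_dson()
  d$multiple_queries[[1]]$near <- "S"
  g <- generate_all(d, generation_options("en"))
  q <- g$multiple_queries[[1]]$query$en
  expect_match(q, "NEAR/S \\(Nitinol")
  expect_match(q, "AND NOT \\(animal OR study OR preclinical\\)$")
})

test_that("generation skips empty languages with a warning issue", {
  d <- build_niti_dson()   # English terms only
  g <- generate_all(d, generation_options(c("en", "de")))
  issues <- attr(g, "generation_issues")
  expect_true(all(issues$severity == "warning"))
  expect_gt(nrow(issues), 0L)
  expect_null(resolve_concept(g, "Nitinol")$query$de)
  expect_false(is.null(resolve_concept(g, "Nitinol")$query$en))

  strict <- generate_all(d, generation_options(c("en", "de"),
                                               skip_empty_concepts = FALSE))
  expect_true(any(attr(strict, "generation_issues")$severity == "error"))
})

test_that("generate_all on an empty dSON is a no-op without issues", {
  g <- generate_all(dson("Empty"))
  expect_equal(length(g$facets), 0L)
  expect_equal(nrow(attr(g, "generation_issues")), 0L)
})

test_that("generation is idempotent and produces balanced, countable queries", {
  for (seed in 1:15) {
    d <- random_dson(seed)
    g1 <- generate_all(d)
    g2 <- generate_all(g1)
    expect_dson_equal(g2, g1)
    for (co in sonq:::all_concepts(g1)) {
      for (lang in names(co$query)) {
        q <- co$query[[lang]]
        chars <- strsplit(gsub('[^()"]', "", q), "")[[1]]
        expect_equal(sum(chars == "("), sum(chars == ")"))
        expect_equal(sum(chars == '"') %% 2, 0)
        if (!co$is_negated) {
          # top-level OR operand count = terms in lang + composites in lang
          ast <- parse_query(q)
          k <- length(Filter(function(t) t$language == lang, co$simple_terms))
          cc <- sum(vapply(g1$composite_terms, function(ct)
            ct$name %in% co$composite_term_refs &&
              !is.null(ct$query[[lang]]), logical(1)))
          expected <- k + cc
          got <- if (ast$kind == "OR") length(ast$children) else 1L
          expect_equal(got, expected)
        }
      }
    }
  }
})

test_that("every generated string parses and renders back unchanged", {
  for (seed in 1:15) {
    g <- generate_all(random_dson(seed))
    queries <- character(0)
    for (co in sonq:::all_concepts(g)) queries <- c(queries, unlist(co$query))
    for (ct in g$composite_terms) queries <- c(queries, unlist(ct$query))
    for (mq in g$multiple_queries) queries <- c(queries, unlist(mq$query))
    for (q in queries) {
      ast <- parse_query(q)
      expect_equal(render_query(ast), q)
    }
  }
})
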