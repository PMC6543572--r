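# Tokenizer, parser and evaluator.

test_that("tokenization segments sentences and paragraphs", {
  doc <- tokenize("Nitinol clip. Unexpected failure.")
  expect_equal(nrow(doc$tokens), 4L)
  expect_equal(doc$tokens$sentence, c(0L, 0L, 1L, 1L))
  expect_equal(unique(doc$tokens$paragraph), 0L)
  expect_equal(doc$tokens$position, 0:3)

  doc2 <- tokenize("First paragraph here.\n\nSecond paragraph there.")
  expect_equal(unique(doc2$tokens$paragraph), c(0L, 1L))

  expect_equal(nrow(tokenize("")$tokens), 0L)
})

test_that("tokenization keeps intra-word hyphens and strips punctuation", {
  doc <- tokenize("A state-of-the-art clip, (really).")
  expect_true("state-of-the-art" %in% doc$tokens$surface)
  expect_false(any(grepl("[(),.]", doc$tokens$surface)))
})

test_that("normalization folds case and diacritics; lexicon fills B and C", {
  lex <- son_lexicon(c("Qualitätskontrollen" = "Qualitätskontrolle"),
                     list("Qualitätskontrollen" = c("Qualität", "Kontrolle")))
  doc <- tokenize("Die Qualitätskontrollen liefen.", lex)
  row <- which(doc$tokens$surface == "Qualitätskontrollen")
  expect_equal(doc$tokens$normalized[row], "qualitatskontrollen")
  expect_equal(doc$tokens$baseform[row], "Qualitätskontrolle")
  expect_equal(doc$tokens$compound_parts[[row]], c("Qualität", "Kontrolle"))
})

test_that("the bundled demo lexicon loads and resolves inflections", {
  lex <- demo_lexicon()
  expect_gte(length(lex$baseform_map), 40L)
  expect_equal(unname(lex$baseform_map[["complications"]]), "complication")
  expect_equal(lex$compound_map[["herzschrittmacher"]],
               c("Herz", "Schrittmacher"))
})

test_that("parsing recovers the printed operator forms", {
  ast <- parse_query("MODE/E (SafeSet)")
  expect_equal(ast$kind, "MODE")
  expect_equal(ast$type, "E")
  expect_equal(ast$children[[1]]$kind, "TERM")
  expect_equal(ast$children[[1]]$text, "SafeSet")

  ast2 <- parse_query(
    "(unexpected OR unforeseeable OR unknown) AND (complication OR failure OR incident)")
  expect_equal(ast2$kind, "AND")
  expect_equal(length(ast2$children), 2L)
  expect_equal(vapply(ast2$children, `[[`, character(1), "kind"),
               c("OR", "OR"))
  expect_equal(lengths(lapply(ast2$children, `[[`, "children")), c(3L, 3L))
})

test_that("syntax errors carry character offsets", {
  err <- tryCatch(parse_query("a AND (b"), error = function(e) e)
  expect_s3_class(err, "sonq_parse_error")
  expect_equal(err$offset, 6L)
  expect_match(conditionMessage(err), "offset 6")
  expect_error(parse_query('a AND "b'), "quote")
  expect_error(parse_query("a OR"), "end of query")
  expect_error(parse_query("NEAR/0 x"), "NEAR")
  expect_error(parse_query("a b AND c"), "trailing")
})

test_that("operators are case-sensitive: lowercase forms are plain terms", {
  # "and" is not an operator, so a second bare term is trailing junk
  err <- tryCatch(parse_query("safety and stent"), error = function(e) e)
  expect_s3_class(err, "sonq_parse_error")
  ok <- parse_query('"safety and stent"')
  expect_equal(ok$kind, "PHRASE")
  expect_true(evaluate(parse_query("and"), tokenize("clips and stents"))$matched)
})

test_that("MODE/E matches exact surfaces only; default D folds case", {
  ast <- parse_query("MODE/E (SafeSet)")
  expect_true(evaluate(ast, tokenize("the SafeSet failed"))$matched)
  expect_false(evaluate(ast, tokenize("the safeset failed"))$matched)
  expect_false(evaluate(ast, tokenize("the SAFESET failed"))$matched)
  plain <- parse_query("SafeSet")
  expect_true(evaluate(plain, tokenize("the safeset failed"))$matched)
  expect_true(evaluate(plain, tokenize("the SAFESET failed"))$matched)
})

test_that("MODE/D strips diacritics and MODE/B, MODE/C use the lexicon", {
  lex <- demo_lexicon()
  doc <- tokenize("Die Zwischenfälle im Herzschrittmacher.", lex)
  expect_true(evaluate(parse_query("zwischenfalle"), doc)$matched)
  expect_true(evaluate(parse_query("MODE/B (Zwischenfall)"), doc)$matched)
  expect_false(evaluate(parse_query("MODE/D (Zwischenfall)"), doc)$matched)
  expect_true(evaluate(parse_query("MODE/C (Schrittmacher)"), doc)$matched)
  expect_false(evaluate(parse_query("MODE/D (Schrittmacher)"), doc)$matched)
})

test_that("wildcards match per the active mode's representation", {
  doc <- tokenize("Nitinol clips failed")
  expect_true(evaluate(parse_query("clip*"), doc)$matched)
  expect_true(evaluate(parse_query("Nit?nol"), doc)$matched)
  expect_false(evaluate(parse_query("sten*"), doc)$matched)
  expect_false(evaluate(parse_query("MODE/E (nitinol*)"),
                        tokenize("Nitinol"))$matched)
  expect_true(evaluate(parse_query("MODE/E (Nitinol*)"),
                       tokenize("Nitinol"))$matched)
})

test_that("phrases match consecutive tokens only", {
  doc <- tokenize("an endoscopic clipping system failed")
  expect_true(evaluate(parse_query('"endoscopic clipping system"'), doc)$matched)
  expect_false(evaluate(parse_query('"endoscopic system"'), doc)$matched)
  r <- evaluate(parse_query('"endoscopic clipping system"'), doc)
  expect_equal(unname(r$spans[1, ]), c(1L, 4L))
})

test_that("NEAR/k distances count token gaps with adjacent = 1", {
  expect_true(evaluate(parse_query("a NEAR/1 b"), tokenize("a b"))$matched)
  expect_false(evaluate(parse_query("a NEAR/1 b"), tokenize("a x b"))$matched)
  expect_true(evaluate(parse_query("a NEAR/2 b"), tokenize("a x b"))$matched)
  expect_true(evaluate(parse_query("b NEAR/2 a"), tokenize("a x b"))$matched)
})

test_that("NEAR/S and NEAR/P respect sentence and paragraph boundaries", {
  same_sent <- tokenize("the clip failed badly today.")
  cross_sent <- tokenize("the clip broke. it failed badly.")
  cross_para <- tokenize("the clip broke.\n\nit failed badly.")
  qs <- parse_query("clip NEAR/S failed")
  qp <- parse_query("clip NEAR/P failed")
  expect_true(evaluate(qs, same_sent)$matched)
  expect_false(evaluate(qs, cross_sent)$matched)
  expect_true(evaluate(qp, cross_sent)$matched)
  expect_false(evaluate(qp, cross_para)$matched)
})

test_that("NEAR spans are hulls, enabling nesting", {
  doc <- tokenize("alpha x beta y gamma")
  r <- evaluate(parse_query("(alpha NEAR/2 beta) NEAR/2 gamma"), doc)
  expect_true(r$matched)
  expect_equal(unname(r$spans[1, ]), c(0L, 5L))
  expect_false(
    evaluate(parse_query("(alpha NEAR/1 beta) NEAR/2 gamma"), doc)$matched)
})

test_that("NOT as a NEAR operand is rejected", {
  doc <- tokenize("a b")
  expect_error(evaluate(parse_query("(NOT a) NEAR/2 b"), doc),
               "unsupported combination")
})

test_that("scores sum boosts over distinct matched occurrences", {
  doc <- tokenize("incident report: another incident")
  r <- evaluate(parse_query("incident^5"), doc)
  expect_equal(r$score, 10)
  r2 <- evaluate(parse_query("incident^5 OR report"), doc)
  expect_equal(r2$score, 11)
  r3 <- evaluate(parse_query("missing OR report"), doc)
  expect_equal(r3$score, 1)
  expect_equal(evaluate(parse_query("missing"), doc)$score, 0)
})

test_that("search ranks by score descending with index tie-break", {
  corpus <- lapply(c("an incident here", "incident and incident again",
                     "nothing relevant"), tokenize)
  hits <- search_corpus(parse_query("incident^5"), corpus)
  expect_equal(hits$doc_index, c(2L, 1L))
  expect_equal(hits$score, c(10, 5))

  both <- search_corpus(parse_query("incident^5"),
                        lapply(c("one incident", "some incident"), tokenize))
  expect_equal(both$doc_index, c(1L, 2L))
  expect_equal(both$score, c(5, 5))

  expect_equal(nrow(search_corpus(parse_query("x"), list())), 0L)
})

test_that("search agrees with per-document evaluation on a synthetic corpus", {
  set.seed(99)
  corpus <- lapply(1:20, function(i) random_doc())
  ast <- parse_query("(stent OR clip) AND failure")
  hits <- search_corpus(ast, corpus)
  expected <- which(vapply(corpus, function(d)
    evaluate(ast, d)$matched, logical(1)))
  expect_setequal(hits$doc_index, expected)
})

test_that("every MODE/E match is also a default-mode match", {
  set.seed(7)
  for (i in 1:50) {
    doc <- random_doc()
    word <- sample(ORACLE_VOCAB, 1)
    e <- evaluate(parse_query(paste0("MODE/E (", word, ")")), doc)$matched
    d <- evaluate(parse_query(word), doc)$matched
    if (e) expect_true(d)
  }
})

test_that("appending AND NOT never enlarges the matched set", {
  set.seed(13)
  corpus <- lapply(1:30, function(i) random_doc())
  base <- "(stent OR failure)"
  with_not <- paste0(base, " AND NOT (animal)")
  m1 <- search_corpus(parse_query(base), corpus)$doc_index
  m2 <- search_corpus(parse_query(with_not), corpus)$doc_index
  expect_true(all(m2 %in% m1))
})
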