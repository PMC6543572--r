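# Brute-force truth-table oracle for query evaluation, written
# independently of the package's span machinery: plain loops over token
# indices, boolean recursion on the AST. NEAR is only supported over
# TERM leaves (the random ASTs below respect that), using pairwise
# position scans.

oracle_word_positions <- function(text, mode, doc) {
  tk <- doc$tokens
  hits <- integer(0)
  for (i in seq_len(nrow(tk))) {
    ok <- switch(
      mode,
      E = identical(tk$surface[i], text),
      D = identical(tk$normalized[i],
                    stringi::stri_trans_general(tolower(text), "Latin-ASCII")),
      B = {
        lex <- unname(doc$lexicon$baseform_map[tolower(text)])
        q <- stringi::stri_trans_general(
          tolower(if (length(lex) == 0L || is.na(lex)) text else lex),
          "Latin-ASCII")
        identical(stringi::stri_trans_general(tolower(tk$baseform[i]),
                                              "Latin-ASCII"), q)
      },
      C = {
        q <- stringi::stri_trans_general(tolower(text), "Latin-ASCII")
        reprs <- c(tk$normalized[i],
                   stringi::stri_trans_general(tolower(tk$compound_parts[[i]]),
                                               "Latin-ASCII"))
        q %in% reprs
      })
    if (ok) hits <- c(hits, tk$position[i])
  }
  hits
}

oracle_eval <- function(node, doc, mode = "D") {
  switch(
    node$kind,
    TERM = length(oracle_word_positions(node$text, mode, doc)) > 0L,
    PHRASE = {
      words <- strsplit(node$text, "\\s+")[[1]]
      sets <- lapply(words, oracle_word_positions, mode = mode, doc = doc)
      any(vapply(sets[[1]], function(p)
        all(vapply(seq_along(sets), function(k)
          (p + k - 1L) %in% sets[[k]], logical(1))), logical(1)))
    },
    AND = all(vapply(node$children, oracle_eval, logical(1),
                     doc = doc, mode = mode)),
    OR = any(vapply(node$children, oracle_eval, logical(1),
                    doc = doc, mode = mode)),
    NOT = !oracle_eval(node$children[[1]], doc, mode),
    MODE = oracle_eval(node$children[[1]], doc, node$type),
    NEAR = {
      p1 <- oracle_word_positions(node$children[[1]]$text, mode, doc)
      p2 <- oracle_word_positions(node$children[[2]]$text, mode, doc)
      found <- FALSE
      for (a in p1) for (b in p2) {
        ok <- if (node$distance == "S") {
          doc$tokens$sentence[doc$tokens$position == a] ==
            doc$tokens$sentence[doc$tokens$position == b]
        } else if (node$distance == "P") {
          doc$tokens$paragraph[doc$tokens$position == a] ==
            doc$tokens$paragraph[doc$tokens$position == b]
        } else {
          abs(a - b) <= as.integer(node$distance)
        }
        if (ok) found <- TRUE
      }
      found
    },
    stop("oracle: unsupported node ", node$kind))
}

ORACLE_VOCAB <- c("stent", "clip", "nitinol", "incident", "failure",
                  "animal", "risk", "device", "safeset", "SafeSet")

random_leaf <- function() {
  if (stats::runif(1) < 0.15) {
    sonq:::ast_node("PHRASE",
                    text = paste(sample(ORACLE_VOCAB, 2), collapse = " "),
                    boost = NULL)
  } else {
    sonq:::ast_node("TERM", text = sample(ORACLE_VOCAB, 1), boost = NULL,
                    wildcard = FALSE)
  }
}

random_ast <- function(depth = 2L) {
  if (depth <= 0L || stats::runif(1) < 0.35) return(random_leaf())
  kind <- sample(c("AND", "OR", "NOT", "NEAR", "MODE"), 1,
                 prob = c(0.3, 0.3, 0.15, 0.15, 0.1))
  switch(
    kind,
    AND = ,
    OR = sonq:::ast_node(kind, children = lapply(
      seq_len(sample(2:3, 1)), function(i) random_ast(depth - 1L))),
    NOT = sonq:::ast_node("NOT", children = list(random_ast(depth - 1L))),
    NEAR = sonq:::ast_node(
      "NEAR", distance = sample(c("1", "2", "4", "S", "P"), 1),
      children = list(
        sonq:::ast_node("TERM", text = sample(ORACLE_VOCAB, 1),
                        boost = NULL, wildcard = FALSE),
        sonq:::ast_node("TERM", text = sample(ORACLE_VOCAB, 1),
                        boost = NULL, wildcard = FALSE))),
    MODE = sonq:::ast_node("MODE", type = sample(c("E", "D", "B", "C"), 1),
                           children = list(random_ast(depth - 1L))))
}

random_doc <- function(lexicon = son_lexicon()) {
  n <- sample(8:25, 1)
  words <- sample(c(ORACLE_VOCAB, "lorem", "ipsum", "dolor"), n,
                  replace = TRUE)
  # sprinkle sentence and paragraph breaks
  seps <- sample(c(" ", " ", " ", ". ", "\n\n"), n - 1, replace = TRUE)
  text <- paste0(words[1], paste0(seps, words[-1], collapse = ""), ".")
  tokenize(text, lexicon)
}
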