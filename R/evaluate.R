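# Span-based query evaluation.
#
# Every AST node evaluates to a match flag, a score and a set of matched
# token spans (half-open [start, end) position intervals). Terms match
# per the active MODE: E compares exact surfaces, D the case-folded
# diacritics-stripped forms (the default), B lexicon baseforms and C also
# compound parts. NEAR/k accepts two child spans whose token gap is at
# most k (adjacent tokens have gap 1); NEAR/S and NEAR/P require both
# spans inside one sentence or paragraph. A NEAR node's own span is the
# hull of the two child spans, which lets NEAR nest.

match_result <- function(matched, score, spans) {
  structure(list(matched = matched, score = score, spans = spans),
            class = "match_result")
}

empty_spans <- function() matrix(integer(0), ncol = 2,
                                 dimnames = list(NULL, c("start", "end")))

#' @export
print.match_result <- function(x, ...) {
  cat("match: ", x$matched, ", score: ", x$score, ", spans: ",
      nrow(x$spans), "\n", sep = "")
  invisible(x)
}

wildcard_regex <- function(pattern) {
  esc <- gsub("([.\\\\+^$(){}\\[\\]|])", "\\\\\\1", pattern, perl = TRUE)
  esc <- gsub("*", ".*", esc, fixed = TRUE)
  esc <- gsub("?", ".", esc, fixed = TRUE)
  paste0("^", esc, "$")
}

query_baseform <- function(text, lexicon) {
  b <- unname(lexicon$baseform_map[tolower(text)])
  if (length(b) == 0L || is.na(b)) normalize_text(text) else normalize_text(b)
}

# Positions (0-based) of tokens matching a single word under `mode`.
match_word_positions <- function(text, mode, doc) {
  tk <- doc$tokens
  if (nrow(tk) == 0L) return(integer(0))
  wildcard <- grepl("[*?]", text)
  if (mode == "E") {
    if (wildcard) return(tk$position[grepl(wildcard_regex(text), tk$surface)])
    return(tk$position[tk$surface == text])
  }
  if (mode == "B") {
    q <- query_baseform(text, doc$lexicon)
    repr <- normalize_text(tk$baseform)
    if (wildcard) return(tk$position[grepl(wildcard_regex(normalize_text(text)), repr)])
    return(tk$position[repr == q])
  }
  q <- normalize_text(text)
  hit <- if (wildcard) grepl(wildcard_regex(q), tk$normalized) else tk$normalized == q
  if (mode == "C") {
    part_hit <- vapply(tk$compound_parts, function(p)
      length(p) > 0L && any((if (wildcard) grepl(wildcard_regex(q), normalize_text(p))
                             else normalize_text(p) == q)), logical(1))
    hit <- hit | part_hit
  }
  tk$position[hit]
}

eval_term <- function(node, mode, doc) {
  pos <- match_word_positions(node$text, mode, doc)
  spans <- if (length(pos)) cbind(start = pos, end = pos + 1L) else empty_spans()
  score <- (node$boost %||% 1) * nrow(spans)
  match_result(nrow(spans) > 0L, score, spans)
}

eval_phrase <- function(node, mode, doc) {
  words <- stringi::stri_extract_all_regex(node$text, TOKEN_REGEX)[[1]]
  words <- words[!is.na(words)]
  if (length(words) == 0L) return(match_result(FALSE, 0, empty_spans()))
  pos_sets <- lapply(words, match_word_positions, mode = mode, doc = doc)
  starts <- pos_sets[[1L]]
  for (k in seq_along(pos_sets)[-1L])
    starts <- starts[(starts + k - 1L) %in% pos_sets[[k]]]
  spans <- if (length(starts))
    cbind(start = starts, end = starts + length(words)) else empty_spans()
  score <- (node$boost %||% 1) * nrow(spans)
  match_result(nrow(spans) > 0L, score, spans)
}

span_gap <- function(s1, s2) {
  if (s2[1] >= s1[2]) return(s2[1] - s1[2] + 1L)
  if (s1[1] >= s2[2]) return(s1[1] - s2[2] + 1L)
  0L
}

# Sentence (or paragraph) index a span lies in; NA if it straddles two.
span_scope <- function(span, doc, field) {
  v <- unique(doc$tokens[[field]][doc$tokens$position >= span[1] &
                                    doc$tokens$position < span[2]])
  if (length(v) == 1L) v else NA_integer_
}

eval_near <- function(node, mode, doc) {
  for (ch in node$children)
    if (ch$kind == "NOT")
      stop("unsupported combination: NOT cannot be an operand of NEAR",
           call. = FALSE)
  r1 <- eval_node(node$children[[1L]], mode, doc)
  r2 <- eval_node(node$children[[2L]], mode, doc)
  if (!r1$matched || !r2$matched)
    return(match_result(FALSE, 0, empty_spans()))
  hulls <- empty_spans()
  dist <- node$distance
  for (i in seq_len(nrow(r1$spans))) {
    s1 <- r1$spans[i, ]
    for (j in seq_len(nrow(r2$spans))) {
      s2 <- r2$spans[j, ]
      ok <- if (dist %in% c("S", "P")) {
        field <- if (dist == "S") "sentence" else "paragraph"
        a <- span_scope(s1, doc, field)
        b <- span_scope(s2, doc, field)
        !is.na(a) && !is.na(b) && a == b
      } else {
        span_gap(s1, s2) <= as.integer(dist)
      }
      if (ok)
        hulls <- rbind(hulls, cbind(start = min(s1[1], s2[1]),
                                    end = max(s1[2], s2[2])))
    }
  }
  hulls <- unique(hulls)
  if (nrow(hulls) == 0L) return(match_result(FALSE, 0, empty_spans()))
  match_result(TRUE, r1$score + r2$score, hulls)
}

eval_node <- function(node, mode, doc) {
  switch(
    node$kind,
    TERM = eval_term(node, mode, doc),
    PHRASE = eval_phrase(node, mode, doc),
    MODE = eval_node(node$children[[1L]], node$type, doc),
    NOT = {
      r <- eval_node(node$children[[1L]], mode, doc)
      match_result(!r$matched, 0, empty_spans())
    },
    AND = {
      rs <- lapply(node$children, eval_node, mode = mode, doc = doc)
      if (all(vapply(rs, `[[`, logical(1), "matched"))) {
        spans <- unique(do.call(rbind, c(list(empty_spans()),
                                         lapply(rs, `[[`, "spans"))))
        match_result(TRUE, sum(vapply(rs, `[[`, numeric(1), "score")), spans)
      } else match_result(FALSE, 0, empty_spans())
    },
    OR = {
      rs <- lapply(node$children, eval_node, mode = mode, doc = doc)
      hit <- vapply(rs, `[[`, logical(1), "matched")
      if (any(hit)) {
        spans <- unique(do.call(rbind, c(list(empty_spans()),
                                         lapply(rs[hit], `[[`, "spans"))))
        match_result(TRUE, sum(vapply(rs[hit], `[[`, numeric(1), "score")),
                     spans)
      } else match_result(FALSE, 0, empty_spans())
    },
    NEAR = eval_near(node, mode, doc),
    stop("unknown AST node kind: ", node$kind))
}

#' Evaluate a query against one tokenized document
#'
#' @param ast a `query_ast` from [parse_query()].
#' @param doc a [tokenize()]d document.
#' @param default_mode term-matching mode active outside any `MODE/X`
#'   wrapper; `"D"` (case-folded, diacritics-normalized) by default.
#' @return a `match_result`: `matched` flag, `score` (sum of boosts,
#'   default 1, over distinct matched term/phrase occurrences; 0 when not
#'   matched) and `spans`, a matrix of half-open `[start, end)` token
#'   position intervals.
#' @export
evaluate <- function(ast, doc, default_mode = "D") {
  stopifnot(inherits(doc, "tokenized_document"),
            default_mode %in% c("E", "D", "B", "C"))
  r <- eval_node(ast, default_mode, doc)
  if (!r$matched) r$score <- 0
  r
}

#' Search a corpus with a query
#'
#' Evaluates the query against every document and returns the matching
#' ones ranked by score (descending, ties by document index ascending).
#'
#' @param ast a `query_ast`.
#' @param corpus list of [tokenize()]d documents.
#' @param default_mode see [evaluate()].
#' @return a data frame with columns `doc_index`, `score` and a list
#'   column `spans`.
#' @export
search_corpus <- function(ast, corpus, default_mode = "D") {
  results <- lapply(corpus, evaluate, ast = ast, default_mode = default_mode)
  hit <- which(vapply(results, `[[`, logical(1), "matched"))
  out <- data.frame(
    doc_index = hit,
    score = vapply(results[hit], `[[`, numeric(1), "score"))
  out$spans <- lapply(results[hit], `[[`, "spans")
  out[order(-out$score, out$doc_index), , drop = FALSE]
}
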