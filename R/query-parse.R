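# Extended Lucene-style query grammar.
#
# Precedence, low to high: OR < AND < NOT < NEAR < MODE < atom.
# Atoms are bare words (optionally with * / ? wildcards and a ^boost),
# double-quoted phrases (optional ^boost) and parenthesized expressions.
# Operators are case-sensitive uppercase: AND, OR, NOT, NEAR/n, NEAR/S,
# NEAR/P, MODE/E, MODE/D, MODE/B, MODE/C. Chained NEAR left-associates.
# Parenthesized sub-expressions keep a `grouped` flag so that rendering a
# parsed query reproduces the original string.

parse_error <- function(msg, offset) {
  stop(structure(class = c("sonq_parse_error", "error", "condition"),
                 list(message = paste0(msg, " at offset ", offset),
                      call = NULL, offset = offset)))
}

# `grouped` counts the explicit parenthesis layers around the node so
# that rendering reproduces the input exactly, including ((x)).
ast_node <- function(kind, ..., grouped = 0L) {
  structure(list(kind = kind, ..., grouped = grouped), class = "query_ast")
}

# --- lexer -----------------------------------------------------------------

# Tokens: list(type, text, boost, offset). Offsets are 0-based character
# positions into the input string.
lex_query <- function(text) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  i <- 1L
  toks <- list()
  push <- function(type, value = NULL, boost = NULL, offset) {
    toks[[length(toks) + 1L]] <<- list(type = type, value = value,
                                       boost = boost, offset = offset)
  }
  read_boost <- function() {
    if (i <= n && chars[i] == "^") {
      start <- i
      i <<- i + 1L
      j <- i
      while (j <= n && grepl("[0-9.]", chars[j])) j <- j + 1L
      raw <- paste0(chars[seq(i, length.out = j - i)], collapse = "")
      if (!grepl("^[0-9]*\\.?[0-9]+$", raw) || as.numeric(raw) <= 0)
        parse_error("invalid boost", start - 1L)
      i <<- j
      return(as.numeric(raw))
    }
    NULL
  }
  while (i <= n) {
    ch <- chars[i]
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    off <- i - 1L
    if (ch == "(") { push("LPAREN", offset = off); i <- i + 1L; next }
    if (ch == ")") { push("RPAREN", offset = off); i <- i + 1L; next }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n && chars[j] != "\"") j <- j + 1L
      if (j > n) parse_error("unbalanced quote opened", off)
      phrase <- paste0(chars[seq(i + 1L, length.out = j - i - 1L)], collapse = "")
      i <- j + 1L
      push("PHRASE", value = phrase, boost = read_boost(), offset = off)
      next
    }
    # bare word up to whitespace, paren or quote
    j <- i
    while (j <= n && !grepl("[\\s()\"]", chars[j], perl = TRUE)) j <- j + 1L
    word <- paste0(chars[seq(i, length.out = j - i)], collapse = "")
    i <- j
    if (word %in% c("AND", "OR", "NOT")) {
      push(word, offset = off)
    } else if (grepl("^NEAR/", word)) {
      v <- tryCatch(parse_near_value(word), error = function(e) NULL)
      if (is.null(v)) parse_error(paste0("invalid NEAR operator '", word, "'"), off)
      push("NEAR", value = v, offset = off)
    } else if (grepl("^MODE/", word)) {
      v <- sub("^MODE/", "", word)
      if (!v %in% c("E", "D", "B", "C"))
        parse_error(paste0("invalid MODE operator '", word, "'"), off)
      push("MODE", value = v, offset = off)
    } else {
      boost <- NULL
      if (grepl("\\^", word)) {
        pos <- regexpr("\\^[^^]*$", word)
        raw <- substr(word, pos + 1L, nchar(word))
        if (!grepl("^[0-9]*\\.?[0-9]+$", raw) || as.numeric(raw) <= 0)
          parse_error(paste0("invalid boost in term '", word, "'"), off)
        boost <- as.numeric(raw)
        word <- substr(word, 1L, pos - 1L)
        if (!nzchar(word)) parse_error("empty term before boost", off)
      }
      push("TERM", value = word, boost = boost, offset = off)
    }
  }
  push("EOF", offset = n)
  toks
}

# --- parser ----------------------------------------------------------------

#' Parse an extended query string into an AST
#'
#' Grammar precedence (low to high): `OR` < `AND` < `NOT` < `NEAR` <
#' `MODE` < atom. `render_query(parse_query(s))` reproduces `s` for every
#' string emitted by the query generator.
#'
#' @param text a query string.
#' @return the root `query_ast` node; kinds are `TERM`, `PHRASE`, `AND`,
#'   `OR`, `NOT`, `NEAR` (distance `"k"`, `"S"` or `"P"`, 2 children) and
#'   `MODE` (type `E`/`D`/`B`/`C`, 1 child).
#' @export
parse_query <- function(text) {
  toks <- lex_query(text)
  pos <- 1L
  peek <- function() toks[[pos]]
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }

  parse_or <- function() {
    kids <- list(parse_and())
    while (peek()$type == "OR") {
      advance()
      kids[[length(kids) + 1L]] <- parse_and()
    }
    if (length(kids) == 1L) kids[[1L]] else ast_node("OR", children = kids)
  }
  parse_and <- function() {
    kids <- list(parse_not())
    while (peek()$type == "AND") {
      advance()
      kids[[length(kids) + 1L]] <- parse_not()
    }
    if (length(kids) == 1L) kids[[1L]] else ast_node("AND", children = kids)
  }
  parse_not <- function() {
    if (peek()$type == "NOT") {
      advance()
      return(ast_node("NOT", children = list(parse_not())))
    }
    parse_near()
  }
  parse_near <- function() {
    left <- parse_mode()
    while (peek()$type == "NEAR") {
      op <- advance()
      right <- parse_mode()
      left <- ast_node("NEAR", distance = op$value,
                       children = list(left, right))
    }
    left
  }
  parse_mode <- function() {
    if (peek()$type == "MODE") {
      op <- advance()
      return(ast_node("MODE", type = op$value, children = list(parse_mode())))
    }
    parse_primary()
  }
  parse_primary <- function() {
    t <- peek()
    if (t$type == "LPAREN") {
      advance()
      inner <- parse_or()
      if (peek()$type != "RPAREN")
        parse_error("unbalanced parenthesis opened", t$offset)
      advance()
      inner$grouped <- (inner$grouped %||% 0L) + 1L
      return(inner)
    }
    if (t$type == "TERM") {
      advance()
      return(ast_node("TERM", text = t$value, boost = t$boost,
                      wildcard = grepl("[*?]", t$value)))
    }
    if (t$type == "PHRASE") {
      advance()
      if (!nzchar(trimws(t$value)))
        parse_error("empty phrase", t$offset)
      return(ast_node("PHRASE", text = t$value, boost = t$boost))
    }
    parse_error(paste0("unexpected ",
                       if (t$type == "EOF") "end of query" else
                         paste0("token '", t$type, "'")),
                t$offset)
  }

  ast <- parse_or()
  t <- peek()
  if (t$type != "EOF")
    parse_error(paste0("unexpected trailing token '", t$type, "'"), t$offset)
  ast
}

node_precedence <- function(node) {
  switch(node$kind, OR = 1L, AND = 2L, NOT = 3L, NEAR = 4L, MODE = 5L, 6L)
}

render_child <- function(child, min_prec) {
  s <- render_query(child)
  if (child$grouped == 0L && node_precedence(child) < min_prec)
    s <- paste0("(", s, ")")
  s
}

#' Render a query AST back to a string
#'
#' Inverse of [parse_query()]: sub-expressions that were parenthesized in
#' the input (or that precedence requires) are wrapped in parentheses.
#'
#' @param ast a `query_ast` node.
#' @return the query string.
#' @export
render_query <- function(ast) {
  out <- switch(
    ast$kind,
    TERM = {
      s <- ast$text
      if (!is.null(ast$boost))
        s <- paste0(s, "^", format(ast$boost, scientific = FALSE, trim = TRUE))
      s
    },
    PHRASE = {
      s <- paste0('"', ast$text, '"')
      if (!is.null(ast$boost))
        s <- paste0(s, "^", format(ast$boost, scientific = FALSE, trim = TRUE))
      s
    },
    OR = paste(vapply(ast$children, render_child, character(1), 2L),
               collapse = " OR "),
    AND = paste(vapply(ast$children, render_child, character(1), 3L),
                collapse = " AND "),
    NOT = paste0("NOT ", render_child(ast$children[[1L]], 3L)),
    NEAR = paste0(render_child(ast$children[[1L]], 4L),
                  " NEAR/", ast$distance, " ",
                  render_child(ast$children[[2L]], 5L)),
    MODE = paste0("MODE/", ast$type, " ",
                  render_child(ast$children[[1L]], 6L)),
    stop("unknown AST node kind: ", ast$kind))
  g <- ast$grouped %||% 0L
  if (g > 0L) paste0(strrep("(", g), out, strrep(")", g)) else out
}

#' @export
print.query_ast <- function(x, ...) {
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    label <- switch(node$kind,
                    TERM = paste0("TERM ", node$text,
                                  if (!is.null(node$boost)) paste0(" ^", node$boost)),
                    PHRASE = paste0("PHRASE \"", node$text, "\""),
                    NEAR = paste0("NEAR/", node$distance),
                    MODE = paste0("MODE/", node$type),
                    node$kind)
    cat(pad, label, "\n", sep = "")
    for (ch in node$children %||% list()) show(ch, indent + 1L)
  }
  show(x, 0L)
  invisible(x)
}
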