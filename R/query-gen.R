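# Query-string generation.
#
# Three layers, generated in order: composite terms (AND- or NEAR-connection
# of the OR-linked simple terms of two concepts), single concept queries
# (OR-connection of all terms of a standard concept; negated OR-connection
# for a negated concept), and multiple concept queries (AND-connection of
# single concept queries). Operand order follows spreadsheet order; all
# operators are uppercase with single-space separation.

#' Query-generation options
#'
#' @param languages character subset of `c("en", "de")`.
#' @param skip_empty_concepts if `TRUE` (default), a concept with no terms
#'   in a requested language yields a warning and no query in that language;
#'   if `FALSE` it is an error issue.
#' @return an object of class `generation_options`.
#' @export
generation_options <- function(languages = c("en", "de"),
                               skip_empty_concepts = TRUE) {
  languages <- match.arg(languages, c("en", "de"), several.ok = TRUE)
  structure(list(languages = languages,
                 skip_empty_concepts = isTRUE(skip_empty_concepts)),
            class = "generation_options")
}

#' Render a term literal as a query fragment
#'
#' Single words are rendered bare, phrases are wrapped in double quotes,
#' and a boost is appended as `^k` after the word or closing quote
#' (e.g. `incident^5`, `"endoscopic clipping system"`).
#'
#' @param term a [son_term()].
#' @return a query fragment string.
#' @export
render_term <- function(term) {
  out <- if (term$is_phrase) paste0('"', term$text, '"') else term$text
  if (!is.null(term$boost))
    out <- paste0(out, "^", format(term$boost, scientific = FALSE, trim = TRUE))
  out
}

terms_in_lang <- function(concept, lang) {
  Filter(function(t) t$language == lang, concept$simple_terms)
}

or_join <- function(operands) paste(operands, collapse = " OR ")

wrap_mode <- function(expr, mode) {
  if (is.null(mode)) expr else paste0("MODE/", mode, " (", expr, ")")
}

near_joiner <- function(near) {
  if (is.null(near)) " AND " else paste0(" NEAR/", near, " ")
}

#' Generate a composite-term query string
#'
#' Produces `(t11 OR t12 ...) AND (t21 OR t22 ...)` from the simple terms
#' of the two part concepts; the joiner becomes `NEAR/k`, `NEAR/S` or
#' `NEAR/P` when the spec sets `near`, and a set `mode` wraps the whole
#' expression as `MODE/X ( ... )`.
#'
#' @param spec a [son_composite()].
#' @param dson the owning [dson()].
#' @param lang `"en"` or `"de"`.
#' @return the query string.
#' @export
generate_composite_term <- function(spec, dson, lang) {
  parts <- lapply(c(spec$part1, spec$part2), function(p) {
    terms <- terms_in_lang(resolve_concept(dson, p), lang)
    if (length(terms) == 0L)
      stop("composite term '", spec$name, "': part concept '", p,
           "' has no simple terms in language '", lang, "'", call. = FALSE)
    paste0("(", or_join(vapply(terms, render_term, character(1))), ")")
  })
  wrap_mode(paste0(parts[[1]], near_joiner(spec$near), parts[[2]]), spec$mode)
}

#' Generate a single-concept query string
#'
#' For a standard concept: the OR-connection of its rendered simple terms
#' and parenthesized composite-term strings, wrapped in parentheses. For a
#' negated concept: `NOT ( ... )` over the OR-connection of its excluded
#' simple terms plus the simple terms of any excluded concepts.
#'
#' @param concept a [son_concept()].
#' @param dson the owning [dson()] (composite terms must already carry
#'   their query strings in `lang`).
#' @param lang `"en"` or `"de"`.
#' @return the query string.
#' @export
generate_single_concept_query <- function(concept, dson, lang) {
  if (concept$is_negated) {
    terms <- terms_in_lang(concept, lang)
    for (r in concept$excluded_concept_refs)
      terms <- c(terms, terms_in_lang(resolve_concept(dson, r), lang))
    if (length(terms) == 0L)
      stop("negated concept '", concept$name, "' has no terms in language '",
           lang, "'", call. = FALSE)
    return(paste0("NOT (", or_join(vapply(terms, render_term, character(1))), ")"))
  }
  operands <- vapply(terms_in_lang(concept, lang), render_term, character(1))
  for (r in concept$composite_term_refs) {
    ct <- Filter(function(s) s$name == r, dson$composite_terms)
    q <- if (length(ct)) ct[[1]]$query[[lang]] else NULL
    if (!is.null(q)) operands <- c(operands, paste0("(", q, ")"))
  }
  if (length(operands) == 0L)
    stop("concept '", concept$name, "' has no terms in language '", lang, "'",
         call. = FALSE)
  paste0("(", or_join(operands), ")")
}

#' Generate a multiple-concept query string
#'
#' Joins the single concept queries of the referenced standard concepts with
#' `AND` (or `NEAR/...` when set -- proximity applies only between standard
#' concepts), appends negated concepts' queries with `AND` (their `NOT` is
#' internal) and applies an optional `MODE` wrapper to the whole expression.
#'
#' @param spec a [son_multi_query()].
#' @param dson the owning [dson()]; single concept queries must be generated.
#' @param lang `"en"` or `"de"`.
#' @param skip_empty drop referenced concepts with no query in `lang`
#'   instead of failing.
#' @return the query string.
#' @export
generate_multiple_concept_query <- function(spec, dson, lang,
                                            skip_empty = TRUE) {
  std <- character(0)
  neg <- character(0)
  for (nm in spec$concepts) {
    co <- resolve_concept(dson, nm)
    q <- co$query[[lang]]
    if (is.null(q)) {
      if (skip_empty) next
      stop("multiple-concept query '", spec$name, "': concept '", nm,
           "' has no query in language '", lang, "'", call. = FALSE)
    }
    if (co$is_negated) neg <- c(neg, q) else std <- c(std, q)
  }
  if (length(std) + length(neg) == 0L)
    stop("multiple-concept query '", spec$name,
         "': no concept yields a query in language '", lang, "'", call. = FALSE)
  if (!is.null(spec$near) && length(std) < 2L)
    stop("multiple-concept query '", spec$name,
         "': NEAR requires at least two standard concepts", call. = FALSE)
  expr <- paste(std, collapse = near_joiner(spec$near))
  if (length(neg)) {
    rest <- paste(neg, collapse = " AND ")
    expr <- if (nzchar(expr)) paste(expr, rest, sep = " AND ") else rest
  }
  wrap_mode(expr, spec$mode)
}

#' Generate all query strings of a dSON
#'
#' Fills the per-language query maps in generation order: composite terms,
#' then single concept queries, then multiple concept queries. Per-item
#' problems are collected without aborting the remaining items; the issue
#' table is attached as attribute `"generation_issues"`. The operation is
#' idempotent.
#'
#' @param dson a [dson()] that passes [validate_dson()].
#' @param options a [generation_options()].
#' @return the dSON with query maps filled.
#' @export
generate_all <- function(dson, options = generation_options()) {
  issues <- list()
  note <- function(sev, loc, msg) issues[[length(issues) + 1L]] <<- issue(sev, loc, msg)
  sev_empty <- if (options$skip_empty_concepts) "warning" else "error"

  dson$composite_terms <- lapply(dson$composite_terms, function(ct) {
    for (lang in options$languages) {
      q <- tryCatch(generate_composite_term(ct, dson, lang),
                    error = function(e) {
                      note(sev_empty, locate(ct), conditionMessage(e))
                      NULL
                    })
      ct$query[[lang]] <- q
    }
    ct
  })

  gen_concept <- function(co) {
    for (lang in options$languages) {
      q <- tryCatch(generate_single_concept_query(co, dson, lang),
                    error = function(e) {
                      note(sev_empty, locate(co), conditionMessage(e))
                      NULL
                    })
      co$query[[lang]] <- q
    }
    co
  }
  dson$facets <- lapply(dson$facets, function(f) {
    f$concepts <- lapply(f$concepts, gen_concept)
    f
  })
  dson$negated_concepts <- lapply(dson$negated_concepts, gen_concept)

  dson$multiple_queries <- lapply(dson$multiple_queries, function(mq) {
    for (lang in options$languages) {
      q <- tryCatch(
        generate_multiple_concept_query(mq, dson, lang,
                                        skip_empty = options$skip_empty_concepts),
        error = function(e) {
          note(sev_empty, locate(mq), conditionMessage(e))
          NULL
        })
      mq$query[[lang]] <- q
    }
    mq
  })

  attr(dson, "generation_issues") <- issue_df(issues)
  dson
}
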