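# SON v2.0 data model: search concepts, search terms and search queries.
#
# A dSON (domain-specific Search Ontology) arranges search concepts into
# facets (one forest per facet), keeps negated concepts in a flat list,
# and carries composite-term and multiple-concept-query specifications.
# All other modules (template I/O, query generation, OWL/JSON serialization,
# the query engine) operate on these types.

#' Create a search term literal
#'
#' A simple term is either a single word (e.g. `clip`, `Nitinol`) or a fixed
#' phrase (e.g. `endoscopic clipping system`). A term may carry a boost
#' multiplier (rendered as `^k`); wildcard characters `*` and `?` are allowed
#' in single-word terms only.
#'
#' @param text term text; leading/trailing whitespace is stripped.
#' @param language `"en"` or `"de"`.
#' @param boost optional positive number.
#' @return an object of class `son_term`.
#' @export
son_term <- function(text, language = "en", boost = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("term text must be non-empty", call. = FALSE)
  if (!language %in% c("en", "de"))
    stop("language must be 'en' or 'de'", call. = FALSE)
  if (!is.null(boost)) {
    boost <- as.numeric(boost)
    if (is.na(boost) || boost <= 0)
      stop("boost must be a positive number", call. = FALSE)
  }
  structure(
    list(text = text, language = language, boost = boost,
         is_phrase = grepl("\\s", text)),
    class = "son_term")
}

#' Create a search concept
#'
#' Standard concepts require their terms to occur in matching documents;
#' negated concepts exclude theirs. Negated concepts may also reference
#' standard concepts whose terms are to be excluded
#' (`excluded_concept_refs`) and never carry composite terms.
#'
#' @param name concept identifier (no whitespace; underscores allowed).
#' @param facet name of the owning facet (`NULL` for negated concepts).
#' @param parent parent concept name within the same facet, or `NULL` for a
#'   facet root.
#' @param simple_terms list of [son_term()] objects.
#' @param composite_term_refs character vector of composite-term names.
#' @param is_negated logical.
#' @param excluded_concept_refs character vector of standard concept names
#'   whose terms a negated concept excludes.
#' @param query named list mapping language to the generated single-concept
#'   query string (filled by [generate_all()]).
#' @param location optional template location string (e.g. `"Material!A3"`).
#' @return an object of class `son_concept`.
#' @export
son_concept <- function(name, facet = NULL, parent = NULL,
                        simple_terms = list(), composite_term_refs = character(),
                        is_negated = FALSE, excluded_concept_refs = character(),
                        query = list(), location = NULL) {
  if (!is_identifier(name))
    stop("concept name must be a whitespace-free identifier: '", name, "'",
         call. = FALSE)
  structure(
    list(name = name, facet = facet, parent = parent,
         simple_terms = simple_terms,
         composite_term_refs = as.character(composite_term_refs),
         is_negated = isTRUE(is_negated),
         excluded_concept_refs = as.character(excluded_concept_refs),
         query = query, location = location),
    class = "son_concept")
}

#' Create a composite-term specification
#'
#' A composite term combines the OR-linked simple terms of two standard
#' concepts into an AND-connection (or a NEAR-connection when `near` is
#' set). Its name is always `part1__part2` with two underscore characters.
#'
#' @param concept name of the concept the composite term describes.
#' @param part1,part2 names of the two standard concepts supplying terms.
#' @param mode optional term-type mode, one of `E`, `D`, `B`, `C`.
#' @param near optional proximity: a positive integer (as number or string),
#'   `"S"` (sentence) or `"P"` (paragraph).
#' @param query named per-language list of generated term strings.
#' @param location optional template location string.
#' @return an object of class `son_composite`.
#' @export
son_composite <- function(concept, part1, part2, mode = NULL, near = NULL,
                          query = list(), location = NULL) {
  stopifnot(is_identifier(concept), is_identifier(part1), is_identifier(part2))
  if (!is.null(mode)) mode <- parse_mode_value(mode)
  if (!is.null(near)) near <- parse_near_value(as.character(near))
  structure(
    list(name = paste0(part1, "__", part2), concept = concept,
         part1 = part1, part2 = part2, mode = mode, near = near,
         query = query, location = location),
    class = "son_composite")
}

#' Create a multiple-concept-query specification
#'
#' A multiple concept query is an AND-connection (or NEAR-connection) of the
#' single concept queries of the selected concepts.
#'
#' @param name query identifier.
#' @param concepts ordered character vector of at least two concept names
#'   (standard and/or negated).
#' @inheritParams son_composite
#' @return an object of class `son_multi_query`.
#' @export
son_multi_query <- function(name, concepts, mode = NULL, near = NULL,
                            query = list(), location = NULL) {
  stopifnot(is_identifier(name))
  if (!is.null(mode)) mode <- parse_mode_value(mode)
  if (!is.null(near)) near <- parse_near_value(as.character(near))
  structure(
    list(name = name, concepts = as.character(concepts), mode = mode,
         near = near, query = query, location = location),
    class = "son_multi_query")
}

#' Create a facet
#'
#' A facet is one axis of the search (e.g. `Material`, `Medical_Device`,
#' `Incident`) holding a forest of standard search concepts. Every
#' non-root concept's parent must precede it in the concept list.
#'
#' @param name facet identifier (used as sheet name in the template).
#' @param concepts ordered list of [son_concept()] objects.
#' @return an object of class `son_facet`.
#' @export
son_facet <- function(name, concepts = list()) {
  stopifnot(is_identifier(name))
  concepts <- lapply(concepts, function(co) { co$facet <- name; co })
  structure(list(name = name, concepts = concepts), class = "son_facet")
}

#' Create a domain-specific search ontology (dSON)
#'
#' @param name ontology identifier (e.g. `dSON-Niti` is written `dSON_Niti`).
#' @param namespace IRI ending in `#` or `/`; defaults to
#'   `http://example.org/dson/<name>#`.
#' @param facets list of [son_facet()] objects.
#' @param negated_concepts flat list of negated [son_concept()] objects.
#' @param composite_terms list of [son_composite()] objects.
#' @param multiple_queries list of [son_multi_query()] objects.
#' @return an object of class `dson`.
#' @export
dson <- function(name, namespace = NULL, facets = list(),
                 negated_concepts = list(), composite_terms = list(),
                 multiple_queries = list()) {
  stopifnot(is_identifier(name))
  if (is.null(namespace))
    namespace <- paste0("http://example.org/dson/", name, "#")
  negated_concepts <- lapply(negated_concepts, function(co) {
    co$is_negated <- TRUE
    co
  })
  structure(
    list(name = name, namespace = namespace, facets = facets,
         negated_concepts = negated_concepts,
         composite_terms = composite_terms,
         multiple_queries = multiple_queries),
    class = "dson")
}

#' @export
print.dson <- function(x, ...) {
  n_con <- sum(vapply(x$facets, function(f) length(f$concepts), integer(1)))
  cat("dSON '", x$name, "' <", x$namespace, ">\n", sep = "")
  cat("  facets:           ", length(x$facets), " (",
      paste(vapply(x$facets, `[[`, character(1), "name"), collapse = ", "),
      ")\n", sep = "")
  cat("  search concepts:  ", n_con, " standard, ",
      length(x$negated_concepts), " negated\n", sep = "")
  cat("  composite terms:  ", length(x$composite_terms), "\n", sep = "")
  cat("  multiple queries: ", length(x$multiple_queries), "\n", sep = "")
  invisible(x)
}

#' @export
print.son_concept <- function(x, ...) {
  kind <- if (x$is_negated) "negated concept" else "search concept"
  cat(kind, " ", x$name, sep = "")
  if (!is.null(x$facet)) cat(" [facet ", x$facet, "]", sep = "")
  cat("\n")
  for (t in x$simple_terms)
    cat("  term (", t$language, "): ", render_term(t), "\n", sep = "")
  for (lang in names(x$query))
    cat("  query (", lang, "): ", x$query[[lang]], "\n", sep = "")
  invisible(x)
}

# All concepts of a dSON (standard first, facet order, then negated).
all_concepts <- function(dson) {
  c(unlist(lapply(dson$facets, `[[`, "concepts"), recursive = FALSE),
    dson$negated_concepts)
}

all_concept_names <- function(dson) {
  vapply(all_concepts(dson), `[[`, character(1), "name")
}

issue <- function(severity, location, message) {
  list(severity = severity, location = location, message = message)
}

issue_df <- function(issues) {
  if (length(issues) == 0L)
    return(data.frame(severity = character(), location = character(),
                      message = character(), stringsAsFactors = FALSE))
  data.frame(
    severity = vapply(issues, `[[`, character(1), "severity"),
    location = vapply(issues, function(i) i$location %||% "", character(1)),
    message = vapply(issues, `[[`, character(1), "message"),
    stringsAsFactors = FALSE)
}

#' Validate a dSON against the model invariants
#'
#' Checks global name uniqueness, parent resolution and the forest property
#' within facets, composite-term well-formedness (distinct standard parts),
#' multiple-query cross-references, negated-concept constraints, term
#' invariants (positive boost, wildcards only in single-word terms) and the
#' namespace IRI shape. Problems are returned, never raised.
#'
#' @param dson a [dson()] object.
#' @return a data frame of issues with columns `severity` (`"error"` or
#'   `"warning"`), `location` and `message`; zero rows iff the dSON is valid.
#' @export
validate_dson <- function(dson) {
  issues <- list()
  add <- function(sev, loc, msg) issues[[length(issues) + 1L]] <<- issue(sev, loc, msg)

  if (!grepl("^[A-Za-z][A-Za-z0-9+.-]*://[^[:space:]]+[#/]$", dson$namespace))
    add("error", "dson", paste0("namespace is not an IRI ending in '#' or '/': ",
                                dson$namespace))

  concepts <- all_concepts(dson)
  names_all <- vapply(concepts, `[[`, character(1), "name")
  dup <- unique(names_all[duplicated(names_all)])
  for (d in dup)
    add("error", locate(concepts[[match(d, names_all)]]),
        paste0("duplicate concept name '", d, "'"))

  standard_names <- unlist(lapply(dson$facets, function(f)
    vapply(f$concepts, `[[`, character(1), "name")))
  negated_names <- vapply(dson$negated_concepts, `[[`, character(1), "name")

  # facet forest: parents exist, precede their children, same facet
  for (f in dson$facets) {
    seen <- character(0)
    for (co in f$concepts) {
      if (!is.null(co$parent) && !(co$parent %in% seen))
        add("error", locate(co),
            paste0("concept '", co$name, "' has parent '", co$parent,
                   "' not declared earlier in facet '", f$name, "'"))
      seen <- c(seen, co$name)
    }
  }

  for (co in concepts) {
    for (t in co$simple_terms) {
      if (t$is_phrase && grepl("[*?]", t$text))
        add("error", locate(co),
            paste0("wildcard in phrase term '", t$text, "' of concept '",
                   co$name, "'"))
    }
    if (co$is_negated) {
      if (length(co$composite_term_refs) > 0L)
        add("error", locate(co),
            paste0("negated concept '", co$name, "' must not have composite terms"))
      for (r in co$excluded_concept_refs)
        if (!r %in% standard_names)
          add("error", locate(co),
              paste0("negated concept '", co$name,
                     "' excludes unknown or non-standard concept '", r, "'"))
    } else if (length(co$excluded_concept_refs) > 0L) {
      add("error", locate(co),
          paste0("standard concept '", co$name, "' cannot exclude concepts"))
    }
  }

  comp_names <- vapply(dson$composite_terms, `[[`, character(1), "name")
  for (ct in dson$composite_terms) {
    if (ct$part1 == ct$part2)
      add("error", locate(ct),
          paste0("composite term '", ct$name, "' has identical parts"))
    for (p in c(ct$concept, ct$part1, ct$part2)) {
      if (!p %in% names_all)
        add("error", locate(ct),
            paste0("composite term '", ct$name, "' references unknown concept '",
                   p, "'"))
      else if (p %in% negated_names && p != ct$concept)
        add("error", locate(ct),
            paste0("composite term '", ct$name, "' part '", p,
                   "' must be a standard concept"))
    }
  }
  for (d in unique(comp_names[duplicated(comp_names)]))
    add("error", "Composite_Term", paste0("duplicate composite term '", d, "'"))

  # composite refs on concepts must resolve
  for (co in concepts)
    for (r in co$composite_term_refs)
      if (!r %in% comp_names)
        add("error", locate(co),
            paste0("concept '", co$name, "' references unknown composite term '",
                   r, "'"))

  mq_names <- vapply(dson$multiple_queries, `[[`, character(1), "name")
  for (d in unique(mq_names[duplicated(mq_names)]))
    add("error", "Multiple_Concept_Query",
        paste0("duplicate multiple-concept query '", d, "'"))
  for (mq in dson$multiple_queries) {
    if (length(mq$concepts) < 2L)
      add("error", locate(mq),
          paste0("multiple-concept query '", mq$name,
                 "' needs at least 2 concepts"))
    for (r in mq$concepts)
      if (!r %in% names_all)
        add("error", locate(mq),
            paste0("multiple-concept query '", mq$name,
                   "' references unknown concept '", r, "'"))
  }

  issue_df(issues)
}

locate <- function(x) x$location %||% x$name

#' Look up a concept by name
#'
#' Searches the facets in order, then the negated concepts.
#'
#' @param dson a validated [dson()].
#' @param name concept identifier.
#' @return the [son_concept()] with that name.
#' @export
resolve_concept <- function(dson, name) {
  for (co in all_concepts(dson))
    if (co$name == name) return(co)
  stop("unknown concept: '", name, "'", call. = FALSE)
}
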