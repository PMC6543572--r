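# JSON serialization of dSONs, used for communication with external
# tools (e.g. a search app rendering the concept tree). One tree per
# facet plus flat negated-concept and multiple-concept-query sections.
# Node key order is fixed: name, type, simple_terms, query, children.
# The shape is described by the JSON Schema shipped at
# inst/extdata/dson-schema.json.

json_terms <- function(terms) {
  list(
    en = vapply(Filter(function(t) t$language == "en", terms),
                render_term, character(1)),
    de = vapply(Filter(function(t) t$language == "de", terms),
                render_term, character(1)))
}

json_query <- function(query) {
  out <- list()
  for (lang in c("en", "de"))
    if (!is.null(query[[lang]])) out[[lang]] <- query[[lang]]
  out
}

json_node <- function(name, type, terms, query, children = list()) {
  list(name = name, type = type, simple_terms = json_terms(terms),
       query = json_query(query), children = children)
}

concept_json_node <- function(concept, facet, composites) {
  kids <- list()
  for (child in facet$concepts)
    if (identical(child$parent, concept$name))
      kids[[length(kids) + 1L]] <- concept_json_node(child, facet, composites)
  for (r in concept$composite_term_refs) {
    ct <- Filter(function(s) s$name == r, composites)
    if (length(ct))
      kids[[length(kids) + 1L]] <-
        json_node(ct[[1]]$name, "composite_term", list(), ct[[1]]$query)
  }
  json_node(concept$name, "concept", concept$simple_terms, concept$query, kids)
}

#' Serialize a dSON to JSON
#'
#' Emits one concept tree per facet (composite terms appear as
#' `composite_term` children of their owning concept) plus
#' `negated_concepts` and `multiple_concept_queries` sections. The output
#' validates against the schema shipped with the package (see
#' [dson_json_schema()]).
#'
#' @param dson a [dson()].
#' @return a JSON string (UTF-8).
#' @export
to_json <- function(dson) {
  facets <- lapply(dson$facets, function(f) {
    roots <- Filter(function(co) is.null(co$parent), f$concepts)
    list(name = f$name,
         concepts = lapply(roots, concept_json_node, facet = f,
                           composites = dson$composite_terms))
  })
  doc <- list(
    name = dson$name,
    facets = facets,
    negated_concepts = lapply(dson$negated_concepts, function(co)
      json_node(co$name, "negated_concept", co$simple_terms, co$query)),
    multiple_concept_queries = lapply(dson$multiple_queries, function(mq)
      json_node(mq$name, "multiple_concept_query", list(), mq$query)))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2))
}

#' Path of the shipped dSON JSON Schema
#'
#' @return file path of `dson-schema.json`.
#' @export
dson_json_schema <- function() {
  system.file("extdata", "dson-schema.json", package = "sonq", mustWork = TRUE)
}

#' Validate a JSON document against a schema subset
#'
#' A minimal structural validator covering the schema features the
#' shipped dSON schema uses: `type`, `properties`, `required`, `items`,
#' `enum` and `additionalProperties`. Intended for checking [to_json()]
#' output; it is not a complete JSON Schema implementation.
#'
#' @param json a JSON string or an already-parsed list.
#' @param schema path to a schema file, a schema JSON string, or a parsed
#'   schema list; defaults to the shipped dSON schema.
#' @return character vector of violations; empty when valid.
#' @export
validate_json <- function(json, schema = dson_json_schema()) {
  parse <- function(x) {
    if (is.character(x) && length(x) == 1L) {
      if (file.exists(x)) jsonlite::read_json(x) else
        jsonlite::parse_json(x)
    } else x
  }
  inst <- parse(json)
  sch <- parse(schema)
  problems <- character(0)
  is_scalar <- function(v, type) {
    switch(type,
           string = is.character(v) && length(v) == 1L,
           number = is.numeric(v) && length(v) == 1L,
           integer = is.numeric(v) && length(v) == 1L && v == as.integer(v),
           boolean = is.logical(v) && length(v) == 1L,
           "null" = is.null(v),
           FALSE)
  }
  check <- function(v, s, path) {
    if (!is.null(s[["$ref"]])) {
      target <- sub("^#/", "", s[["$ref"]])
      s <- sch[[strsplit(target, "/", fixed = TRUE)[[1]]]]
    }
    type <- s[["type"]]
    if (!is.null(s[["enum"]])) {
      if (!any(vapply(s[["enum"]], identical, logical(1), v)))
        problems <<- c(problems, paste0(path, ": value not in enum"))
      return(invisible())
    }
    if (is.null(type)) return(invisible())
    if (type == "object") {
      if (!is.list(v) || (length(v) > 0L && is.null(names(v)))) {
        problems <<- c(problems, paste0(path, ": expected object"))
        return(invisible())
      }
      for (req in s[["required"]] %||% list())
        if (!req %in% names(v))
          problems <<- c(problems, paste0(path, ": missing required key '",
                                          req, "'"))
      props <- s[["properties"]] %||% list()
      for (k in names(v)) {
        if (k %in% names(props)) {
          check(v[[k]], props[[k]], paste0(path, ".", k))
        } else if (identical(s[["additionalProperties"]], FALSE)) {
          problems <<- c(problems, paste0(path, ": unexpected key '", k, "'"))
        }
      }
    } else if (type == "array") {
      if (!is.list(v) && !(is.vector(v) && is.null(names(v)))) {
        problems <<- c(problems, paste0(path, ": expected array"))
        return(invisible())
      }
      if (is.list(v) && !is.null(names(v)) && length(v) > 0L) {
        problems <<- c(problems, paste0(path, ": expected array, got object"))
        return(invisible())
      }
      it <- s[["items"]]
      if (!is.null(it))
        for (i in seq_along(v)) check(v[[i]], it, paste0(path, "[", i, "]"))
    } else if (!is_scalar(v, type)) {
      problems <<- c(problems, paste0(path, ": expected ", type))
    }
  }
  check(inst, sch, "$")
  problems
}
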