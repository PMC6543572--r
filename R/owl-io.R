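# OWL serialization of dSONs.
#
# The emitted document always contains the SON base vocabulary -- 9
# classes and 13 annotation properties -- in the ontology's own namespace,
# plus the domain classes: facet concept trees under Standard_Concept,
# negated concepts under Negated_Concept, composite-term classes under
# Composite_Term and multiple-concept-query classes under
# Multiple_Concept_Query. Terms and queries are language-tagged
# annotation literals. RDF/XML is the canonical syntax; a Turtle subset
# is accepted on read. Bookkeeping that the SON vocabulary cannot express
# (facet membership, the ontology's short name) travels in a separate
# metadata namespace so the SON class/property counts stay exact.

SON_CLASSES <- c(
  "Search_Concept", "Standard_Concept", "Negated_Concept",
  "Search_Term", "Simple_Term", "Composite_Term",
  "Search_Query", "Single_Concept_Query", "Multiple_Concept_Query")

SON_PROPERTIES <- c(
  "described_by", "has_part", "has_terms_of_concept_as_part",
  "has_term_of_concept_as_part_1", "has_term_of_concept_as_part_2",
  "has_query_of_concept_as_part", "simple_term", "composite_term",
  "query", "excluded_concept", "excluded_simple_term", "mode", "near")

SON_SUBCLASS <- c(
  Standard_Concept = "Search_Concept", Negated_Concept = "Search_Concept",
  Simple_Term = "Search_Term", Composite_Term = "Search_Term",
  Single_Concept_Query = "Search_Query",
  Multiple_Concept_Query = "Search_Query")

META_NS <- "http://son-generator.org/meta#"

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"

#' The SON base vocabulary
#'
#' @param namespace IRI prefix the names are minted under.
#' @return a list with character vectors `classes` (9) and `properties`
#'   (13), each IRI being `namespace + name`.
#' @export
son_vocabulary <- function(namespace = "http://example.org/dson/SON#") {
  list(classes = paste0(namespace, SON_CLASSES),
       properties = paste0(namespace, SON_PROPERTIES))
}

local_name <- function(iri) sub(".*[#/]", "", iri)

ensure_generated <- function(dson) {
  has_content <- function(x) length(x$simple_terms %||% list()) > 0L ||
    length(x$composite_term_refs %||% character(0)) > 0L
  for (co in all_concepts(dson))
    if (has_content(co) && length(co$query) == 0L)
      stop("ungenerated queries: concept '", co$name,
           "' has terms but no query; run generate_all() first", call. = FALSE)
  for (ct in dson$composite_terms)
    if (length(ct$query) == 0L)
      stop("ungenerated queries: composite term '", ct$name,
           "' has no query; run generate_all() first", call. = FALSE)
}

#' Serialize a generated dSON to OWL (RDF/XML)
#'
#' @param dson a [dson()] whose queries were filled by [generate_all()].
#' @return an `xml2::xml_document`; write it with [xml2::write_xml()].
#' @export
to_owl <- function(dson) {
  ensure_generated(dson)
  ns <- dson$namespace
  doc <- xml2::xml_new_root(
    "rdf:RDF",
    "xmlns:rdf" = RDF_NS, "xmlns:rdfs" = RDFS_NS, "xmlns:owl" = OWL_NS,
    "xmlns:son" = ns, "xmlns:meta" = META_NS)

  onto <- xml2::xml_add_child(doc, "owl:Ontology",
                              "rdf:about" = sub("[#/]$", "", ns))
  xml2::xml_add_child(onto, "meta:dson_name", dson$name)

  for (cl in SON_CLASSES) {
    node <- xml2::xml_add_child(doc, "owl:Class", "rdf:about" = paste0(ns, cl))
    if (cl %in% names(SON_SUBCLASS))
      xml2::xml_add_child(node, "rdfs:subClassOf",
                          "rdf:resource" = paste0(ns, SON_SUBCLASS[[cl]]))
  }
  for (pr in SON_PROPERTIES)
    xml2::xml_add_child(doc, "owl:AnnotationProperty",
                        "rdf:about" = paste0(ns, pr))

  add_terms <- function(node, terms, property) {
    for (t in terms)
      xml2::xml_add_child(node, property, render_term(t), "xml:lang" = t$language)
  }
  add_queries <- function(node, query) {
    for (lang in names(query))
      if (!is.null(query[[lang]]))
        xml2::xml_add_child(node, "son:query", query[[lang]], "xml:lang" = lang)
  }

  for (f in dson$facets) {
    for (co in f$concepts) {
      node <- xml2::xml_add_child(doc, "owl:Class",
                                  "rdf:about" = paste0(ns, co$name))
      parent <- if (is.null(co$parent)) "Standard_Concept" else co$parent
      xml2::xml_add_child(node, "rdfs:subClassOf",
                          "rdf:resource" = paste0(ns, parent))
      xml2::xml_add_child(node, "meta:facet", f$name)
      add_terms(node, co$simple_terms, "son:simple_term")
      for (r in co$composite_term_refs)
        xml2::xml_add_child(node, "son:composite_term",
                            "rdf:resource" = paste0(ns, r))
      add_queries(node, co$query)
    }
  }

  for (co in dson$negated_concepts) {
    node <- xml2::xml_add_child(doc, "owl:Class",
                                "rdf:about" = paste0(ns, co$name))
    xml2::xml_add_child(node, "rdfs:subClassOf",
                        "rdf:resource" = paste0(ns, "Negated_Concept"))
    add_terms(node, co$simple_terms, "son:excluded_simple_term")
    for (r in co$excluded_concept_refs)
      xml2::xml_add_child(node, "son:excluded_concept",
                          "rdf:resource" = paste0(ns, r))
    add_queries(node, co$query)
  }

  for (ct in dson$composite_terms) {
    node <- xml2::xml_add_child(doc, "owl:Class",
                                "rdf:about" = paste0(ns, ct$name))
    xml2::xml_add_child(node, "rdfs:subClassOf",
                        "rdf:resource" = paste0(ns, "Composite_Term"))
    xml2::xml_add_child(node, "son:has_term_of_concept_as_part_1",
                        "rdf:resource" = paste0(ns, ct$part1))
    xml2::xml_add_child(node, "son:has_term_of_concept_as_part_2",
                        "rdf:resource" = paste0(ns, ct$part2))
    if (!is.null(ct$mode)) xml2::xml_add_child(node, "son:mode", ct$mode)
    if (!is.null(ct$near)) xml2::xml_add_child(node, "son:near", ct$near)
    add_queries(node, ct$query)
  }

  for (mq in dson$multiple_queries) {
    node <- xml2::xml_add_child(doc, "owl:Class",
                                "rdf:about" = paste0(ns, mq$name))
    xml2::xml_add_child(node, "rdfs:subClassOf",
                        "rdf:resource" = paste0(ns, "Multiple_Concept_Query"))
    for (r in mq$concepts)
      xml2::xml_add_child(node, "son:has_query_of_concept_as_part",
                          "rdf:resource" = paste0(ns, r))
    if (!is.null(mq$mode)) xml2::xml_add_child(node, "son:mode", mq$mode)
    if (!is.null(mq$near)) xml2::xml_add_child(node, "son:near", mq$near)
    add_queries(node, mq$query)
  }

  doc
}

# --- generic RDF reading ---------------------------------------------------
# Subjects are represented as ordered lists:
#   list(iri, types = character(), props = list(list(pred, value, lang,
#        resource)))  -- props in document order.

read_rdf_subjects <- function(x) {
  if (inherits(x, "xml_document")) return(rdf_subjects_xml(x))
  if (is.character(x) && length(x) == 1L) {
    content <- if (file.exists(x)) {
      paste(readLines(x, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    } else x
    if (grepl("^\\s*<", content))
      return(rdf_subjects_xml(xml2::read_xml(content)))
    return(rdf_subjects_turtle(content))
  }
  stop("cannot read RDF from object of class ", class(x)[1], call. = FALSE)
}

expand_qname <- function(qname, ns_map) {
  parts <- strsplit(qname, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(parts)
  uri <- ns_map[[parts[1]]]
  if (is.null(uri) || is.na(uri)) return(qname)
  paste0(uri, paste(parts[-1], collapse = ":"))
}

attr_get <- function(node, local) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == local | endsWith(names(at), paste0(":", local)))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

rdf_subjects_xml <- function(doc) {
  ns_map <- xml2::xml_ns(doc)
  subjects <- list()
  for (node in xml2::xml_children(doc)) {
    iri <- attr_get(node, "about")
    if (is.na(iri)) next
    type_uri <- expand_qname(xml2::xml_name(node, ns_map), ns_map)
    types <- if (type_uri == paste0(RDF_NS, "Description")) character(0) else type_uri
    props <- list()
    for (child in xml2::xml_children(node)) {
      pred <- expand_qname(xml2::xml_name(child, ns_map), ns_map)
      res <- attr_get(child, "resource")
      if (pred == paste0(RDF_NS, "type") && !is.na(res)) {
        types <- c(types, res)
        next
      }
      props[[length(props) + 1L]] <- list(
        pred = pred,
        value = if (is.na(res)) xml2::xml_text(child) else res,
        lang = attr_get(child, "lang"),
        resource = !is.na(res))
    }
    subjects[[length(subjects) + 1L]] <-
      list(iri = iri, types = types, props = props)
  }
  subjects
}

# Minimal Turtle reader: @prefix declarations, subject blocks with ";"
# and "," separators, IRIs in <>, prefixed names, string literals with an
# optional @lang tag, and the "a" keyword. Sufficient for label
# ontologies and SONG output re-serialized by standard tools.
rdf_subjects_turtle <- function(text) {
  toks <- turtle_tokens(text)
  prefixes <- list()
  subjects <- list()
  index <- new.env(parent = emptyenv())
  resolve <- function(tok) {
    if (startsWith(tok, "<")) return(substr(tok, 2L, nchar(tok) - 1L))
    pos <- regexpr(":", tok, fixed = TRUE)
    if (pos < 1L)
      stop("expected IRI or prefixed name in Turtle input: '", tok, "'",
           call. = FALSE)
    # prefix keys are prefixed with "pfx_" so the empty prefix indexes too
    base <- prefixes[[paste0("pfx_", substr(tok, 1L, pos - 1L))]]
    if (is.null(base))
      stop("undeclared Turtle prefix '", substr(tok, 1L, pos - 1L), ":'",
           call. = FALSE)
    paste0(base, substr(tok, pos + 1L, nchar(tok)))
  }
  i <- 1L
  n <- length(toks)
  get_subject <- function(iri) {
    key <- paste0("s", iri)
    id <- index[[key]]
    if (is.null(id)) {
      subjects[[length(subjects) + 1L]] <<-
        list(iri = iri, types = character(0), props = list())
      id <- length(subjects)
      index[[key]] <- id
    }
    id
  }
  while (i <= n) {
    if (toks[i] %in% c("@prefix", "PREFIX")) {
      pfx <- sub(":$", "", toks[i + 1L])
      prefixes[[paste0("pfx_", pfx)]] <-
        substr(toks[i + 2L], 2L, nchar(toks[i + 2L]) - 1L)
      i <- i + if (toks[i] == "@prefix") 4L else 3L
      next
    }
    sid <- get_subject(resolve(toks[i]))
    i <- i + 1L
    repeat {
      pred_tok <- toks[i]
      pred <- if (pred_tok == "a") paste0(RDF_NS, "type") else resolve(pred_tok)
      i <- i + 1L
      repeat {
        obj <- toks[i]
        i <- i + 1L
        if (startsWith(obj, "\"")) {
          lang <- NA_character_
          if (grepl("\"@[A-Za-z-]+$", obj)) {
            lang <- sub(".*\"@", "", obj)
            obj <- sub("@[A-Za-z-]+$", "", obj)
          }
          val <- substr(obj, 2L, nchar(obj) - 1L)
          subjects[[sid]]$props[[length(subjects[[sid]]$props) + 1L]] <-
            list(pred = pred, value = val, lang = lang, resource = FALSE)
        } else {
          iri <- resolve(obj)
          if (pred == paste0(RDF_NS, "type")) {
            subjects[[sid]]$types <- c(subjects[[sid]]$types, iri)
          } else {
            subjects[[sid]]$props[[length(subjects[[sid]]$props) + 1L]] <-
              list(pred = pred, value = iri, lang = NA_character_,
                   resource = TRUE)
          }
        }
        if (i > n || toks[i] != ",") break
        i <- i + 1L
      }
      if (i > n || toks[i] != ";") break
      i <- i + 1L
      if (i > n || toks[i] == ".") break   # trailing semicolon
    }
    if (i <= n && toks[i] == ".") i <- i + 1L
  }
  subjects
}

turtle_tokens <- function(text) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  toks <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (grepl("\\s", ch)) { i <- i + 1L; next }
    if (ch == "#") {
      while (i <= n && chars[i] != "\n") i <- i + 1L
      next
    }
    if (ch == "<") {
      j <- i
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) stop("unterminated IRI in Turtle input", call. = FALSE)
      toks <- c(toks, paste0(chars[i:j], collapse = ""))
      i <- j + 1L
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n && chars[j] != "\"") {
        if (chars[j] == "\\") j <- j + 1L
        j <- j + 1L
      }
      if (j > n) stop("unterminated literal in Turtle input", call. = FALSE)
      # optional @lang or ^^type suffix glued to the literal token
      k <- j + 1L
      if (k <= n && chars[k] == "@") {
        while (k <= n && grepl("[A-Za-z@-]", chars[k])) k <- k + 1L
        j <- k - 1L
      }
      toks <- c(toks, paste0(chars[i:j], collapse = ""))
      i <- j + 1L
      next
    }
    if (ch %in% c(";", ",", ".")) {
      # "." only terminates a statement when followed by whitespace/EOF
      if (ch != "." || i == n || grepl("\\s", chars[i + 1L])) {
        toks <- c(toks, ch)
        i <- i + 1L
        next
      }
    }
    j <- i
    while (j <= n && !grepl("[\\s;,]", chars[j], perl = TRUE) &&
           !(chars[j] == "." && (j == n || grepl("\\s", chars[j + 1L]))))
      j <- j + 1L
    toks <- c(toks, paste0(chars[i:(j - 1L)], collapse = ""))
    i <- j
  }
  toks
}

# --- reading a dSON back ---------------------------------------------------

parse_term_fragment <- function(text, lang) {
  boost <- NULL
  if (grepl('^".*"(\\^[0-9.]+)?$', text)) {
    m <- regmatches(text, regexec('^"(.*)"(?:\\^([0-9.]+))?$', text))[[1]]
    if (nzchar(m[3])) boost <- as.numeric(m[3])
    return(son_term(m[2], language = lang, boost = boost))
  }
  if (grepl("\\^[0-9.]+$", text)) {
    pos <- regexpr("\\^[0-9.]+$", text)
    boost <- as.numeric(substr(text, pos + 1L, nchar(text)))
    text <- substr(text, 1L, pos - 1L)
  }
  son_term(text, language = lang, boost = boost)
}

prop_values <- function(subject, pred_iri) {
  Filter(function(p) p$pred == pred_iri, subject$props)
}

#' Read a dSON from an OWL document
#'
#' Inverse of [to_owl()] (up to annotation ordering). Accepts an
#' `xml2::xml_document`, a file path or a string holding RDF/XML or
#' Turtle. Classes that fall under no SON base class are skipped with a
#' warning; unknown annotation properties are ignored with a warning.
#'
#' @param x OWL input.
#' @return a [dson()].
#' @export
from_owl <- function(x) {
  subjects <- read_rdf_subjects(x)
  iris <- vapply(subjects, `[[`, character(1), "iri")

  anchor <- grep("[#/]Search_Concept$", iris, value = TRUE)
  if (length(anchor) == 0L)
    stop("missing SON vocabulary: no Search_Concept class found", call. = FALSE)
  ns <- sub("Search_Concept$", "", anchor[[1]])
  son_iri <- function(name) paste0(ns, name)
  for (required in c("Standard_Concept", "Negated_Concept", "Composite_Term",
                     "Multiple_Concept_Query"))
    if (!son_iri(required) %in% iris)
      stop("missing SON vocabulary: class ", required, " absent", call. = FALSE)

  name <- "dSON"
  onto <- Filter(function(s) any(s$types == paste0(OWL_NS, "Ontology")), subjects)
  if (length(onto)) {
    nm <- prop_values(onto[[1]], paste0(META_NS, "dson_name"))
    if (length(nm)) name <- nm[[1]]$value
  }

  class_subjects <- Filter(function(s)
    any(s$types == paste0(OWL_NS, "Class")) && startsWith(s$iri, ns) &&
      !local_name(s$iri) %in% SON_CLASSES, subjects)

  parent_of <- function(s) {
    sc <- prop_values(s, paste0(RDFS_NS, "subClassOf"))
    vapply(sc, `[[`, character(1), "value")
  }
  # classify by walking subclass links up to a SON base class
  by_iri <- stats::setNames(class_subjects,
                            vapply(class_subjects, `[[`, character(1), "iri"))
  base_of <- function(iri, seen = character(0)) {
    if (local_name(iri) %in% SON_CLASSES) return(local_name(iri))
    if (iri %in% seen) return(NA_character_)
    s <- by_iri[[iri]]
    if (is.null(s)) return(NA_character_)
    for (p in parent_of(s)) {
      b <- base_of(p, c(seen, iri))
      if (!is.na(b)) return(b)
    }
    NA_character_
  }

  known_preds <- c(paste0(ns, SON_PROPERTIES), paste0(RDFS_NS, "subClassOf"),
                   paste0(RDFS_NS, "label"), paste0(RDFS_NS, "comment"),
                   paste0(META_NS, c("facet", "dson_name")))

  read_queries <- function(s) {
    out <- list()
    for (p in prop_values(s, son_iri("query"))) {
      lang <- if (is.na(p$lang)) "en" else p$lang
      out[[lang]] <- p$value
    }
    out
  }
  read_terms <- function(s, property) {
    lapply(prop_values(s, son_iri(property)), function(p)
      parse_term_fragment(p$value, if (is.na(p$lang)) "en" else p$lang))
  }

  facet_names <- character(0)
  facet_concepts <- list()
  negated <- list()
  composites <- list()
  multis <- list()

  for (s in class_subjects) {
    for (p in s$props)
      if (!p$pred %in% known_preds)
        warning("ignoring unknown annotation ", p$pred, " on ",
                local_name(s$iri), call. = FALSE)
    base <- base_of(s$iri)
    nm <- local_name(s$iri)
    if (is.na(base)) {
      warning("skipping class '", nm, "' under no SON base class",
              call. = FALSE)
      next
    }
    if (base %in% c("Standard_Concept", "Search_Concept")) {
      parents <- setdiff(parent_of(s), son_iri(c("Standard_Concept",
                                                 "Search_Concept")))
      parent <- if (length(parents)) local_name(parents[[1]]) else NULL
      fx <- prop_values(s, paste0(META_NS, "facet"))
      facet <- if (length(fx)) fx[[1]]$value else "Imported"
      refs <- vapply(prop_values(s, son_iri("composite_term")),
                     function(p) local_name(p$value), character(1))
      co <- son_concept(nm, facet = facet, parent = parent,
                        simple_terms = read_terms(s, "simple_term"),
                        composite_term_refs = refs, query = read_queries(s))
      if (!facet %in% facet_names) {
        facet_names <- c(facet_names, facet)
        facet_concepts[[facet]] <- list()
      }
      facet_concepts[[facet]] <- c(facet_concepts[[facet]], list(co))
    } else if (base == "Negated_Concept") {
      refs <- vapply(prop_values(s, son_iri("excluded_concept")),
                     function(p) local_name(p$value), character(1))
      negated[[length(negated) + 1L]] <- son_concept(
        nm, simple_terms = read_terms(s, "excluded_simple_term"),
        is_negated = TRUE, excluded_concept_refs = refs,
        query = read_queries(s))
    } else if (base == "Composite_Term") {
      p1 <- prop_values(s, son_iri("has_term_of_concept_as_part_1"))
      p2 <- prop_values(s, son_iri("has_term_of_concept_as_part_2"))
      if (length(p1) == 0L || length(p2) == 0L) {
        warning("skipping composite term '", nm, "' without part annotations",
                call. = FALSE)
        next
      }
      md <- prop_values(s, son_iri("mode"))
      nr <- prop_values(s, son_iri("near"))
      composites[[length(composites) + 1L]] <- son_composite(
        concept = nm,   # rewired below from the referencing concept
        part1 = local_name(p1[[1]]$value), part2 = local_name(p2[[1]]$value),
        mode = if (length(md)) md[[1]]$value else NULL,
        near = if (length(nr)) nr[[1]]$value else NULL,
        query = read_queries(s))
    } else if (base == "Multiple_Concept_Query") {
      refs <- vapply(prop_values(s, son_iri("has_query_of_concept_as_part")),
                     function(p) local_name(p$value), character(1))
      md <- prop_values(s, son_iri("mode"))
      nr <- prop_values(s, son_iri("near"))
      multis[[length(multis) + 1L]] <- son_multi_query(
        nm, concepts = refs,
        mode = if (length(md)) md[[1]]$value else NULL,
        near = if (length(nr)) nr[[1]]$value else NULL,
        query = read_queries(s))
    } else {
      warning("skipping class '", nm, "' under unsupported base ", base,
              call. = FALSE)
    }
  }

  # composite owner = the concept referencing it via composite_term
  owner <- list()
  for (fn in facet_names)
    for (co in facet_concepts[[fn]])
      for (r in co$composite_term_refs) owner[[r]] <- co$name
  composites <- lapply(composites, function(ct) {
    ct$concept <- owner[[ct$name]] %||% ct$concept
    ct
  })

  dson(name, namespace = ns,
       facets = lapply(facet_names, function(fn)
         son_facet(fn, facet_concepts[[fn]])),
       negated_concepts = negated, composite_terms = composites,
       multiple_queries = multis)
}

#' Import an external label ontology as a facet
#'
#' Treats any ontology whose classes carry `rdfs:label` annotations as a
#' source of search concepts: each class becomes a concept, subclass
#' axioms become parent links, language-tagged labels become simple terms
#' and a label-less class falls back to its IRI local name as its single
#' term. A class with several superclasses is attached to the first seen,
#' with a warning.
#'
#' @param x OWL input (RDF/XML or Turtle; document, path or string).
#' @param facet_name name of the created facet.
#' @return a [son_facet()].
#' @export
import_external_ontology <- function(x, facet_name) {
  subjects <- read_rdf_subjects(x)
  classes <- Filter(function(s)
    any(s$types == paste0(OWL_NS, "Class")) ||
      length(prop_values(s, paste0(RDFS_NS, "subClassOf"))) > 0L, subjects)
  if (length(classes) == 0L)
    stop("empty ontology: no classes with labels found", call. = FALSE)
  iris <- vapply(classes, `[[`, character(1), "iri")

  make_concept <- function(s, parent) {
    labels <- prop_values(s, paste0(RDFS_NS, "label"))
    labels <- Filter(function(p) is.na(p$lang) || p$lang %in% c("en", "de"),
                     labels)
    terms <- lapply(labels, function(p)
      son_term(p$value, language = if (is.na(p$lang)) "en" else p$lang))
    nm <- gsub("[^A-Za-z0-9_]+", "_", local_name(s$iri))
    if (length(terms) == 0L)
      terms <- list(son_term(local_name(s$iri), language = "en"))
    son_concept(nm, facet = facet_name, parent = parent, simple_terms = terms)
  }

  parent_iri <- vapply(classes, function(s) {
    sc <- prop_values(s, paste0(RDFS_NS, "subClassOf"))
    sc <- Filter(function(p) p$value %in% iris, sc)
    if (length(sc) == 0L) return(NA_character_)
    if (length(sc) > 1L)
      warning("class '", local_name(s$iri),
              "' has multiple superclasses; attached to first seen",
              call. = FALSE)
    sc[[1]]$value
  }, character(1))

  # emit parents before children (stable Kahn ordering)
  placed <- character(0)
  concepts <- list()
  remaining <- seq_along(classes)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i)
      is.na(parent_iri[i]) || parent_iri[i] %in% placed, logical(1))]
    if (length(ready) == 0L) {  # cycle: break it by placing the first as root
      ready <- remaining[1L]
      parent_iri[ready] <- NA_character_
      warning("subclass cycle detected; breaking at '",
              local_name(classes[[ready]]$iri), "'", call. = FALSE)
    }
    for (i in ready) {
      parent <- if (is.na(parent_iri[i])) NULL else
        gsub("[^A-Za-z0-9_]+", "_", local_name(parent_iri[i]))
      concepts[[length(concepts) + 1L]] <- make_concept(classes[[i]], parent)
      placed <- c(placed, classes[[i]]$iri)
    }
    remaining <- setdiff(remaining, ready)
  }
  son_facet(facet_name, concepts)
}
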