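# Programmatic test-input builders: the dSON-Niti example (unexpected
# side effects of Nitinol in endoscopic clipping systems), and seeded
# synthetic corpora with planted term occurrences whose ground-truth
# match labels are computed from the recipe arithmetic, independently of
# the query engine.

#' Build the dSON-Niti example ontology
#'
#' Facets `Material` (Nitinol with its synonyms), `Medical_Device`
#' (clip/stent/occluder/implant subdivision, with the endoscopic clipping
#' system under clip) and `Incident` (Unexpected_Complication described
#' by the composite term of Unexpected and Complication), the negated
#' concept `No_Preclinical` (animal/study/preclinical) and one multiple
#' concept query combining Unexpected_Complication, Nitinol,
#' Endoscopic_Clipping_System and No_Preclinical. Queries are not yet
#' generated; English terms only.
#'
#' @return a valid [dson()].
#' @export
build_niti_dson <- function() {
  en <- function(...) lapply(c(...), son_term, language = "en")
  material <- son_facet("Material", list(
    son_concept("Nitinol",
                simple_terms = en("Nitinol", "Nickel Titanium", "NiTi"))))
  device <- son_facet("Medical_Device", list(
    son_concept("Clip", simple_terms = en("clip")),
    son_concept("Endoscopic_Clipping_System", parent = "Clip",
                simple_terms = en("endoscopic clipping system")),
    son_concept("Stent", simple_terms = en("stent")),
    son_concept("Occluder", simple_terms = en("occluder")),
    son_concept("PFO_Occluder", parent = "Occluder",
                simple_terms = en("PFO occluder")),
    son_concept("PDA_Occluder", parent = "Occluder",
                simple_terms = en("PDA occluder")),
    son_concept("Implant", simple_terms = en("implant"))))
  incident <- son_facet("Incident", list(
    son_concept("Unexpected",
                simple_terms = en("unexpected", "unforeseeable", "unknown")),
    son_concept("Complication",
                simple_terms = en("complication", "failure", "incident")),
    son_concept("Unexpected_Complication",
                composite_term_refs = "Unexpected__Complication")))
  dson(
    "dSON_Niti",
    facets = list(material, device, incident),
    negated_concepts = list(
      son_concept("No_Preclinical", is_negated = TRUE,
                  simple_terms = en("animal", "study", "preclinical"))),
    composite_terms = list(
      son_composite(concept = "Unexpected_Complication",
                    part1 = "Unexpected", part2 = "Complication")),
    multiple_queries = list(
      son_multi_query("Niti_Query",
                      concepts = c("Unexpected_Complication", "Nitinol",
                                   "Endoscopic_Clipping_System",
                                   "No_Preclinical"))))
}

#' Write the dSON-Niti example workbook
#'
#' @param path output `.xlsx` path (default: temporary file).
#' @return the workbook path, invisibly.
#' @export
build_niti_workbook <- function(path = file.path(tempdir(), "dSON_Niti.xlsx")) {
  write_template(build_niti_dson(), path)
}

# Filler vocabulary, disjoint from every fixture concept term so that
# planted occurrences are the only matches.
FILLER_WORDS <- c(
  "lorem", "ipsum", "dolor", "amet", "consectetur", "adipiscing", "elit",
  "tempor", "labore", "dolore", "magna", "aliqua", "enim", "minim",
  "veniam", "quis", "nostrud", "ullamco", "laboris", "nisi", "aliquip",
  "commodo", "consequat", "aute", "irure", "voluptate", "velit", "esse",
  "cillum", "fugiat")

#' Create a synthetic-corpus recipe
#'
#' Two kinds of seeded corpora are supported. `"proximity"` documents
#' plant the two words of `pair` at a controlled token distance (`gap`,
#' drawn from `1:max_gap`) in one of three placements -- within one
#' sentence, across sentences of one paragraph, or across paragraphs --
#' or omit the second word entirely; ground truth records the gap and
#' placement. `"niti"` documents independently plant the dSON-Niti query
#' ingredients (an unexpected-complication sentence, a Nitinol mention,
#' the endoscopic clipping system phrase) and, in some documents, a
#' preclinical/animal/study term; ground truth is whether the multiple
#' concept query should match.
#'
#' @param n_docs number of documents.
#' @param seed integer random seed; a fixed seed yields byte-identical
#'   documents.
#' @param kind `"proximity"` or `"niti"`.
#' @param pair the two planted words for proximity corpora.
#' @param max_gap largest planted token gap.
#' @return an object of class `corpus_recipe`.
#' @export
corpus_recipe <- function(n_docs, seed = 1L, kind = c("proximity", "niti"),
                          pair = c("unexpected", "complication"),
                          max_gap = 8L) {
  kind <- match.arg(kind)
  stopifnot(n_docs >= 0L, length(pair) == 2L, max_gap >= 1L)
  structure(list(n_docs = as.integer(n_docs), seed = as.integer(seed),
                 kind = kind, pair = pair, max_gap = as.integer(max_gap)),
            class = "corpus_recipe")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed",
                                                envir = globalenv()))
          else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

filler <- function(n) paste(sample(FILLER_WORDS, n, replace = TRUE),
                            collapse = " ")
filler_sentence <- function() paste0(filler(sample(4:8, 1L)), ".")

# A sentence containing a, then gap-1 interior fillers, then b.
planted_sentence <- function(a, b, gap) {
  mid <- if (gap > 1L) paste0(" ", filler(gap - 1L)) else ""
  paste0(filler(sample(1:3, 1L)), " ", a, mid, " ", b, " ",
         filler(sample(1:3, 1L)), ".")
}

# Two chunks whose concatenation puts b exactly `gap` token positions
# after a; the break between them falls between the two planted words.
planted_split <- function(a, b, gap) {
  after_a <- if (gap > 1L) sample(0:(gap - 1L), 1L) else 0L
  before_b <- gap - 1L - after_a
  first <- paste0(filler(sample(1:3, 1L)), " ", a,
                  if (after_a > 0L) paste0(" ", filler(after_a)), ".")
  second <- paste0(if (before_b > 0L) paste0(filler(before_b), " "),
                   b, " ", filler(sample(1:3, 1L)), ".")
  c(first, second)
}

#' Build a synthetic corpus with ground-truth labels
#'
#' @param recipe a [corpus_recipe()].
#' @return a list with `texts` (character vector of documents) and
#'   `labels`, a data frame of per-document ground truth: for proximity
#'   corpora `gap` (NA when a word is missing), `same_sentence` and
#'   `same_paragraph`; for niti corpora `has_incident`, `has_material`,
#'   `has_device`, `has_negated` and `expected_match`.
#' @export
build_corpus <- function(recipe) {
  stopifnot(inherits(recipe, "corpus_recipe"))
  with_seed(recipe$seed, {
    if (recipe$kind == "proximity") build_proximity_corpus(recipe)
    else build_niti_corpus(recipe)
  })
}

build_proximity_corpus <- function(recipe) {
  texts <- character(recipe$n_docs)
  gap <- integer(recipe$n_docs)
  same_sentence <- logical(recipe$n_docs)
  same_paragraph <- logical(recipe$n_docs)
  a <- recipe$pair[1]
  b <- recipe$pair[2]
  for (i in seq_len(recipe$n_docs)) {
    placement <- sample(c("sentence", "paragraph", "document", "missing"),
                        1L, prob = c(0.4, 0.25, 0.25, 0.1))
    g <- sample.int(recipe$max_gap, 1L)
    lead <- filler_sentence()
    tail_ <- filler_sentence()
    if (placement == "sentence") {
      body <- planted_sentence(a, b, g)
      texts[i] <- paste0(lead, " ", body, "\n\n", tail_)
      gap[i] <- g
      same_sentence[i] <- TRUE
      same_paragraph[i] <- TRUE
    } else if (placement == "paragraph") {
      chunks <- planted_split(a, b, g)
      texts[i] <- paste0(lead, " ", chunks[1], " ", chunks[2], "\n\n", tail_)
      gap[i] <- g
      same_sentence[i] <- FALSE
      same_paragraph[i] <- TRUE
    } else if (placement == "document") {
      chunks <- planted_split(a, b, g)
      texts[i] <- paste0(lead, " ", chunks[1], "\n\n", chunks[2], " ", tail_)
      gap[i] <- g
      same_sentence[i] <- FALSE
      same_paragraph[i] <- FALSE
    } else {
      texts[i] <- paste0(lead, " ", planted_sentence(a, FILLER_WORDS[1], 2L),
                         "\n\n", tail_)
      gap[i] <- NA_integer_
      same_sentence[i] <- FALSE
      same_paragraph[i] <- FALSE
    }
  }
  list(texts = texts,
       labels = data.frame(gap = gap, same_sentence = same_sentence,
                           same_paragraph = same_paragraph))
}

build_niti_corpus <- function(recipe) {
  n <- recipe$n_docs
  texts <- character(n)
  has_incident <- logical(n)
  has_material <- logical(n)
  has_device <- logical(n)
  has_negated <- logical(n)
  for (i in seq_len(n)) {
    has_incident[i] <- stats::runif(1) < 0.7
    has_material[i] <- stats::runif(1) < 0.7
    has_device[i] <- stats::runif(1) < 0.7
    has_negated[i] <- stats::runif(1) < 0.3
    sentences <- c(filler_sentence(), filler_sentence())
    if (has_incident[i])
      sentences <- c(sentences, planted_sentence(
        sample(c("unexpected", "unforeseeable", "unknown"), 1L),
        sample(c("complication", "failure", "incident"), 1L),
        sample.int(3L, 1L)))
    if (has_material[i])
      sentences <- c(sentences, paste0(
        filler(2L), " ", sample(c("Nitinol", "Nickel Titanium", "NiTi"), 1L),
        " ", filler(2L), "."))
    if (has_device[i])
      sentences <- c(sentences, paste0(
        filler(2L), " endoscopic clipping system ", filler(2L), "."))
    if (has_negated[i])
      sentences <- c(sentences, paste0(
        filler(2L), " ", sample(c("animal", "study", "preclinical"), 1L),
        " ", filler(2L), "."))
    sentences <- sample(sentences)
    split_at <- sample(seq_len(length(sentences) - 1L), 1L)
    texts[i] <- paste0(paste(sentences[seq_len(split_at)], collapse = " "),
                       "\n\n",
                       paste(sentences[-seq_len(split_at)], collapse = " "))
  }
  list(texts = texts,
       labels = data.frame(
         has_incident = has_incident, has_material = has_material,
         has_device = has_device, has_negated = has_negated,
         expected_match = has_incident & has_material & has_device &
           !has_negated))
}
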