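# Seeded random model instances for property-style tests, and a
# structural equality helper that ignores provenance-only fields.

TERM_POOL <- c(
  "alpha", "beta", "gamma", "delta", "epsilon", "zeta", "theta", "kappa",
  "lambda", "sigma", "omega", "krypton", "argon", "neon", "helium",
  "radon", "cobalt", "nickel", "titan", "ferrum")

random_term <- function(lang) {
  n <- sample(1:3, 1, prob = c(0.7, 0.2, 0.1))
  text <- paste(sample(TERM_POOL, n), collapse = " ")
  boost <- if (stats::runif(1) < 0.2) sample(c(2, 5, 0.5), 1) else NULL
  if (n == 1L && stats::runif(1) < 0.15) text <- paste0(text, "*")
  son_term(text, language = lang, boost = boost)
}

# A valid dSON with random facet forests (concept lists in pre-order),
# negated concepts, composite terms and multiple-concept queries. Every
# concept gets at least one English term so each query map is non-empty.
random_dson <- function(seed) {
  set.seed(seed)
  counter <- 0L
  new_name <- function(prefix) {
    counter <<- counter + 1L
    paste0(prefix, "_", counter)
  }

  facets <- lapply(seq_len(sample(1:3, 1)), function(fi) {
    n <- sample(1:5, 1)
    concepts <- list()
    path <- character(0)   # ancestor chain of the previous concept
    for (i in seq_len(n)) {
      keep <- sample(0:min(length(path), 2L), 1)
      path <- path[seq_len(keep)]
      nm <- new_name("Concept")
      terms <- lapply(seq_len(sample(1:3, 1)), function(j) random_term("en"))
      if (stats::runif(1) < 0.6)
        terms <- c(terms, lapply(seq_len(sample(1:2, 1)),
                                 function(j) random_term("de")))
      concepts[[i]] <- son_concept(
        nm, parent = if (keep > 0L) path[keep] else NULL,
        simple_terms = terms)
      path <- c(path, nm)
    }
    son_facet(new_name("Facet"), concepts)
  })

  standard_names <- unlist(lapply(facets, function(f)
    vapply(f$concepts, `[[`, character(1), "name")))

  negated <- lapply(seq_len(sample(0:2, 1)), function(i) {
    refs <- if (stats::runif(1) < 0.4 && length(standard_names))
      sample(standard_names, 1) else character(0)
    son_concept(new_name("No"), is_negated = TRUE,
                simple_terms = lapply(seq_len(sample(1:3, 1)),
                                      function(j) random_term("en")),
                excluded_concept_refs = refs)
  })

  composites <- list()
  if (length(standard_names) >= 2L) {
    n_ct <- sample(0:2, 1)
    pairs <- list()
    for (i in seq_len(n_ct)) {
      pr <- sort(sample(standard_names, 2))
      key <- paste(pr, collapse = "|")
      if (key %in% names(pairs)) next
      pairs[[key]] <- pr
      composites[[length(composites) + 1L]] <- son_composite(
        concept = sample(standard_names, 1), part1 = pr[1], part2 = pr[2],
        mode = if (stats::runif(1) < 0.3) sample(c("E", "D", "B", "C"), 1) else NULL,
        near = if (stats::runif(1) < 0.3) sample(c("3", "S", "P"), 1) else NULL)
    }
  }

  all_names <- c(standard_names,
                 vapply(negated, `[[`, character(1), "name"))
  multis <- list()
  for (i in seq_len(sample(0:2, 1))) {
    use_near <- stats::runif(1) < 0.3 && length(standard_names) >= 2L
    refs <- if (use_near) sample(standard_names, 2) else
      sample(all_names, min(length(all_names), sample(2:3, 1)))
    if (length(refs) < 2L) next
    multis[[length(multis) + 1L]] <- son_multi_query(
      new_name("Query"), concepts = refs,
      mode = if (stats::runif(1) < 0.2) "E" else NULL,
      near = if (use_near) sample(c("4", "S", "P"), 1) else NULL)
  }

  d <- dson(paste0("Random_", seed), facets = facets,
            negated_concepts = negated, composite_terms = composites,
            multiple_queries = multis)
  sonq:::attach_composite_refs(d)
}

# Drop provenance-only fields and class attributes before comparing models.
strip_dson <- function(x) {
  strip <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v))) v <- v[names(v) != "location"]
      return(lapply(v, strip))   # lapply keeps names, drops class
    }
    unname(v)
  }
  strip(x)
}

expect_dson_equal <- function(a, b) {
  expect_equal(strip_dson(a), strip_dson(b))
}
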