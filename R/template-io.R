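# Reading and writing the dSON specification workbook.
#
# The workbook holds three reserved sheets -- Negated_Concept,
# Composite_Term and Multiple_Concept_Query -- and any number of
# user-defined facet sheets. Facet sheets encode the concept hierarchy in
# depth columns: a concept's name sits in exactly one of the leading
# columns (all columns left of "Simple Terms (en)"), and its parent is the
# nearest preceding row whose name sits in a shallower column. Simple
# terms are ";"-separated within a cell, with an optional trailing ^boost.

RESERVED_SHEETS <- c("Negated_Concept", "Composite_Term", "Multiple_Concept_Query")

template_error <- function(msg) {
  stop(structure(class = c("sonq_template_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

read_sheet_grid <- function(path, sheet) {
  g <- suppressMessages(
    readxl::read_xlsx(path, sheet = sheet, col_names = FALSE, col_types = "text"))
  as.matrix(g)
}

# Locate a header (trimmed, case-sensitive) in the first row; 0 if absent.
header_col <- function(grid, name) {
  if (nrow(grid) == 0L) return(0L)
  hits <- which(!is.na(grid[1, ]) & trimws(grid[1, ]) == name)
  if (length(hits) == 0L) 0L else unname(hits[1L])
}

header_cols_all <- function(grid, name) {
  if (nrow(grid) == 0L) return(integer(0))
  unname(which(!is.na(grid[1, ]) & trimws(grid[1, ]) == name))
}

cell <- function(grid, r, j) {
  if (j == 0L || j > ncol(grid) || r > nrow(grid)) return(NA_character_)
  grid[r, j]
}

# ";"-separated term cell -> list of son_term; trailing ^number is a boost.
parse_term_cell <- function(text, language, where) {
  if (is.na(text) || !nzchar(trimws(text))) return(list())
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    p <- trimws(p)
    if (!nzchar(p)) next
    boost <- NULL
    if (grepl("\\^", p)) {
      pos <- regexpr("\\^[^^]*$", p)
      raw <- substr(p, pos + 1L, nchar(p))
      word <- trimws(substr(p, 1L, pos - 1L))
      if (!grepl("^[0-9]*\\.?[0-9]+$", raw) || as.numeric(raw) <= 0 || !nzchar(word))
        template_error(paste0("malformed boost '", p, "' at ", where))
      boost <- as.numeric(raw)
      p <- word
    }
    out[[length(out) + 1L]] <- son_term(p, language = language, boost = boost)
  }
  out
}

#' Read a dSON from a specification workbook
#'
#' Parses the facet sheets (in sheet order, rows in row order), the
#' `Negated_Concept`, `Composite_Term` and `Multiple_Concept_Query` sheets
#' into a [dson()] with query strings unfilled. Concept cell text is
#' normalized to identifiers with [normalize_identifier()].
#'
#' @param path path to an `.xlsx` workbook.
#' @param name ontology name; defaults to the file base name, normalized.
#' @param namespace ontology namespace IRI; defaults to
#'   `http://example.org/dson/<name>#`.
#' @return a [dson()] (run [validate_dson()] and [generate_all()] next).
#' @export
read_template <- function(path, name = NULL, namespace = NULL) {
  if (!file.exists(path)) stop("workbook not found: ", path, call. = FALSE)
  if (is.null(name))
    name <- normalize_identifier(gsub("[^A-Za-z0-9_]+", "_",
                                      tools::file_path_sans_ext(basename(path))))
  sheet_names <- readxl::excel_sheets(path)
  for (req in RESERVED_SHEETS)
    if (!req %in% sheet_names)
      template_error(paste0("missing required sheet '", req, "'"))

  facet_sheets <- setdiff(sheet_names, RESERVED_SHEETS)
  facets <- lapply(facet_sheets, function(sn)
    read_facet_sheet(read_sheet_grid(path, sn), sn))
  negated <- read_negated_sheet(read_sheet_grid(path, "Negated_Concept"))
  composites <- read_composite_sheet(read_sheet_grid(path, "Composite_Term"))
  multis <- read_multi_query_sheet(read_sheet_grid(path, "Multiple_Concept_Query"))

  d <- dson(name, namespace = namespace, facets = facets,
            negated_concepts = negated, composite_terms = composites,
            multiple_queries = multis)
  attach_composite_refs(d)
}

# Link each composite term to its owning concept (row order).
attach_composite_refs <- function(d) {
  by_concept <- split(
    vapply(d$composite_terms, `[[`, character(1), "name"),
    vapply(d$composite_terms, `[[`, character(1), "concept"))
  d$facets <- lapply(d$facets, function(f) {
    f$concepts <- lapply(f$concepts, function(co) {
      co$composite_term_refs <- as.character(by_concept[[co$name]] %||% character(0))
      co
    })
    f
  })
  d
}

read_facet_sheet <- function(grid, sheet_name) {
  facet_name <- normalize_identifier(sheet_name)
  if (nrow(grid) == 0L)
    return(son_facet(facet_name))
  en_col <- header_col(grid, "Simple Terms (en)")
  de_col <- header_col(grid, "Simple Terms (de)")
  if (en_col == 0L && de_col == 0L)
    template_error(paste0("sheet '", sheet_name,
                          "' lacks a 'Simple Terms (en)' or 'Simple Terms (de)' column"))
  first_term_col <- min(c(en_col, de_col)[c(en_col, de_col) > 0L])
  depth_cols <- seq_len(first_term_col - 1L)
  if (length(depth_cols) == 0L)
    template_error(paste0("sheet '", sheet_name, "' has no concept columns"))

  concepts <- list()
  seen <- character(0)      # names in row order
  seen_depth <- integer(0)
  seen_where <- character(0)
  for (r in seq_len(nrow(grid))[-1]) {
    filled <- depth_cols[!is.na(grid[r, depth_cols]) &
                           nzchar(trimws(grid[r, depth_cols]))]
    if (length(filled) == 0L) next   # blank row
    if (length(filled) > 1L)
      template_error(paste0("sheet '", sheet_name, "' row ", r,
                            ": concept name in more than one depth column"))
    depth <- match(filled, depth_cols)
    cname <- normalize_identifier(grid[r, filled])
    where <- paste0(sheet_name, "!", col_letter(filled), r)
    if (cname %in% seen)
      template_error(paste0("duplicate concept name '", cname, "' at ", where,
                            " and ", seen_where[match(cname, seen)]))
    parent <- NULL
    if (depth > 1L) {
      shallower <- which(seen_depth < depth)
      if (length(shallower) == 0L)
        template_error(paste0("concept '", cname, "' at ", where,
                              " has depth ", depth, " but no preceding parent"))
      parent <- seen[max(shallower)]
    }
    terms <- c(
      parse_term_cell(cell(grid, r, en_col), "en",
                      paste0(sheet_name, "!", col_letter(en_col), r)),
      parse_term_cell(cell(grid, r, de_col), "de",
                      paste0(sheet_name, "!", col_letter(de_col), r)))
    concepts[[length(concepts) + 1L]] <-
      son_concept(cname, facet = facet_name, parent = parent,
                  simple_terms = terms, location = where)
    seen <- c(seen, cname)
    seen_depth <- c(seen_depth, depth)
    seen_where <- c(seen_where, where)
  }
  son_facet(facet_name, concepts)
}

read_negated_sheet <- function(grid) {
  if (nrow(grid) == 0L) return(list())
  ccol <- header_col(grid, "Concept")
  if (ccol == 0L)
    template_error("sheet 'Negated_Concept' lacks a 'Concept' column")
  en_col <- header_col(grid, "Excluded Simple Terms (en)")
  de_col <- header_col(grid, "Excluded Simple Terms (de)")
  legacy <- header_col(grid, "Excluded Simple Terms")
  if (en_col == 0L) en_col <- legacy   # legacy single column read as English
  xcol <- header_col(grid, "Excluded Concepts")

  out <- list()
  for (r in seq_len(nrow(grid))[-1]) {
    raw <- cell(grid, r, ccol)
    if (is.na(raw) || !nzchar(trimws(raw))) next
    cname <- normalize_identifier(raw)
    where <- paste0("Negated_Concept!", col_letter(ccol), r)
    terms <- c(
      parse_term_cell(cell(grid, r, en_col), "en",
                      paste0("Negated_Concept!", col_letter(en_col), r)),
      parse_term_cell(cell(grid, r, de_col), "de",
                      paste0("Negated_Concept!", col_letter(de_col), r)))
    refs <- character(0)
    xraw <- cell(grid, r, xcol)
    if (!is.na(xraw) && nzchar(trimws(xraw)))
      refs <- normalize_identifier(trimws(strsplit(xraw, ";", fixed = TRUE)[[1]]))
    out[[length(out) + 1L]] <-
      son_concept(cname, simple_terms = terms, is_negated = TRUE,
                  excluded_concept_refs = refs[nzchar(refs)], location = where)
  }
  out
}

read_composite_sheet <- function(grid) {
  if (nrow(grid) == 0L) return(list())
  cols <- c(Concept = header_col(grid, "Concept"),
            part1 = header_col(grid, "part1"),
            part2 = header_col(grid, "part2"))
  for (nm in names(cols))
    if (cols[[nm]] == 0L)
      template_error(paste0("sheet 'Composite_Term' lacks a '", nm, "' column"))
  mcol <- header_col(grid, "MODE")
  ncol_ <- header_col(grid, "NEAR")

  out <- list()
  for (r in seq_len(nrow(grid))[-1]) {
    raw <- cell(grid, r, cols[["Concept"]])
    if (is.na(raw) || !nzchar(trimws(raw))) next
    where <- paste0("Composite_Term!", col_letter(cols[["Concept"]]), r)
    p1 <- cell(grid, r, cols[["part1"]])
    p2 <- cell(grid, r, cols[["part2"]])
    if (is.na(p1) || is.na(p2) || !nzchar(trimws(p1)) || !nzchar(trimws(p2)))
      template_error(paste0("composite term at ", where, " lacks part1/part2"))
    out[[length(out) + 1L]] <- son_composite(
      concept = normalize_identifier(raw),
      part1 = normalize_identifier(p1), part2 = normalize_identifier(p2),
      mode = na_null(cell(grid, r, mcol)), near = na_null(cell(grid, r, ncol_)),
      location = where)
  }
  out
}

read_multi_query_sheet <- function(grid) {
  if (nrow(grid) == 0L) return(list())
  qcol <- header_col(grid, "Query")
  if (qcol == 0L)
    template_error("sheet 'Multiple_Concept_Query' lacks a 'Query' column")
  mcol <- header_col(grid, "MODE")
  ncol_ <- header_col(grid, "NEAR")
  ccols <- header_cols_all(grid, "Concept")
  if (length(ccols) == 0L)
    template_error("sheet 'Multiple_Concept_Query' lacks 'Concept' columns")

  out <- list()
  for (r in seq_len(nrow(grid))[-1]) {
    raw <- cell(grid, r, qcol)
    if (is.na(raw) || !nzchar(trimws(raw))) next
    where <- paste0("Multiple_Concept_Query!", col_letter(qcol), r)
    refs <- character(0)
    for (j in ccols) {
      v <- cell(grid, r, j)
      if (!is.na(v) && nzchar(trimws(v)))
        refs <- c(refs, normalize_identifier(v))
    }
    out[[length(out) + 1L]] <- son_multi_query(
      name = normalize_identifier(raw), concepts = refs,
      mode = na_null(cell(grid, r, mcol)), near = na_null(cell(grid, r, ncol_)),
      location = where)
  }
  out
}

na_null <- function(x) if (is.null(x) || length(x) == 0L || is.na(x)) NULL else x

# --- writing ---------------------------------------------------------------

render_term_cell <- function(terms, language) {
  sel <- Filter(function(t) t$language == language, terms)
  if (length(sel) == 0L) return(NA_character_)
  paste(vapply(sel, function(t) {
    if (is.null(t$boost)) t$text else paste0(t$text, "^", format(t$boost))
  }, character(1)), collapse = "; ")
}

concept_depth <- function(concepts_by_name, name) {
  d <- 1L
  cur <- concepts_by_name[[name]]
  while (!is.null(cur$parent)) {
    d <- d + 1L
    cur <- concepts_by_name[[cur$parent]]
  }
  d
}

# Pre-order traversal of a facet forest, children in declaration order.
facet_preorder <- function(facet) {
  nms <- vapply(facet$concepts, `[[`, character(1), "name")
  children <- lapply(nms, function(n)
    which(vapply(facet$concepts, function(co)
      identical(co$parent, n), logical(1))))
  names(children) <- nms
  roots <- which(vapply(facet$concepts, function(co) is.null(co$parent), logical(1)))
  out <- integer(0)
  visit <- function(i) {
    out <<- c(out, i)
    for (j in children[[nms[i]]]) visit(j)
  }
  for (i in roots) visit(i)
  facet$concepts[out]
}

#' Write a dSON to a specification workbook
#'
#' Inverse of [read_template()]: facet sheets are written with the concept
#' hierarchy in depth columns (rows in pre-order), followed by the three
#' reserved sheets. `read_template(write_template(d))` reproduces `d` for
#' any valid dSON whose facet concept lists are in pre-order.
#'
#' @param dson a valid [dson()].
#' @param path output `.xlsx` path; defaults to `<name>.xlsx` in a
#'   temporary directory.
#' @return the path, invisibly.
#' @export
write_template <- function(dson, path = NULL) {
  if (is.null(path)) path <- file.path(tempdir(), paste0(dson$name, ".xlsx"))
  sheets <- list()

  for (f in dson$facets) {
    ordered <- facet_preorder(f)
    by_name <- stats::setNames(ordered, vapply(ordered, `[[`, character(1), "name"))
    depths <- vapply(names(by_name), function(n) concept_depth(by_name, n),
                     integer(1))
    h <- max(1L, depths)
    m <- matrix(NA_character_, nrow = length(ordered) + 1L, ncol = h + 2L)
    m[1, 1] <- "Concept"
    m[1, h + 1L] <- "Simple Terms (en)"
    m[1, h + 2L] <- "Simple Terms (de)"
    for (i in seq_along(ordered)) {
      co <- ordered[[i]]
      m[i + 1L, depths[[i]]] <- co$name
      m[i + 1L, h + 1L] <- render_term_cell(co$simple_terms, "en")
      m[i + 1L, h + 2L] <- render_term_cell(co$simple_terms, "de")
    }
    sheets[[f$name]] <- m
  }

  neg <- dson$negated_concepts
  m <- matrix(NA_character_, nrow = length(neg) + 1L, ncol = 4L)
  m[1, ] <- c("Concept", "Excluded Simple Terms (en)",
              "Excluded Simple Terms (de)", "Excluded Concepts")
  for (i in seq_along(neg)) {
    co <- neg[[i]]
    m[i + 1L, 1] <- co$name
    m[i + 1L, 2] <- render_term_cell(co$simple_terms, "en")
    m[i + 1L, 3] <- render_term_cell(co$simple_terms, "de")
    if (length(co$excluded_concept_refs))
      m[i + 1L, 4] <- paste(co$excluded_concept_refs, collapse = "; ")
  }
  sheets[["Negated_Concept"]] <- m

  ct <- dson$composite_terms
  m <- matrix(NA_character_, nrow = length(ct) + 1L, ncol = 5L)
  m[1, ] <- c("Concept", "part1", "part2", "MODE", "NEAR")
  for (i in seq_along(ct)) {
    s <- ct[[i]]
    m[i + 1L, 1:3] <- c(s$concept, s$part1, s$part2)
    if (!is.null(s$mode)) m[i + 1L, 4] <- s$mode
    if (!is.null(s$near)) m[i + 1L, 5] <- s$near
  }
  sheets[["Composite_Term"]] <- m

  mq <- dson$multiple_queries
  maxc <- max(c(1L, vapply(mq, function(q) length(q$concepts), integer(1))))
  m <- matrix(NA_character_, nrow = length(mq) + 1L, ncol = 3L + maxc)
  m[1, 1:3] <- c("Query", "MODE", "NEAR")
  m[1, 3L + seq_len(maxc)] <- rep("Concept", maxc)
  for (i in seq_along(mq)) {
    q <- mq[[i]]
    m[i + 1L, 1] <- q$name
    if (!is.null(q$mode)) m[i + 1L, 2] <- q$mode
    if (!is.null(q$near)) m[i + 1L, 3] <- q$near
    m[i + 1L, 3L + seq_along(q$concepts)] <- q$concepts
  }
  sheets[["Multiple_Concept_Query"]] <- m

  write_xlsx_sheets(sheets, path)
  invisible(path)
}
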