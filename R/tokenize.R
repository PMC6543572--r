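# Document tokenization with sentence/paragraph segmentation and
# term-type annotation.
#
# Paragraphs are split on blank lines, sentences on . ! ? followed by
# whitespace, tokens on whitespace and punctuation (intra-word hyphens are
# kept). Each token carries four representations used by the MODE term
# types: the exact surface (E), the case-folded diacritics-stripped
# normalized form (D), a lemmatized baseform (B, via the lexicon) and
# compound parts (C, via the lexicon).

#' Create a lexicon
#'
#' Maps surface forms to baseforms (lemmatization) and to compound parts
#' (word decomposition). Lookup keys are case-folded. With an empty
#' lexicon, baseform matching (MODE/B) falls back to normalized matching
#' and compound matching (MODE/C) to no splitting.
#'
#' @param baseform_map named character vector, surface -> baseform.
#' @param compound_map named list, surface -> character vector of parts.
#' @return an object of class `son_lexicon`.
#' @export
son_lexicon <- function(baseform_map = character(), compound_map = list()) {
  if (length(baseform_map)) {
    stopifnot(!is.null(names(baseform_map)), all(nzchar(baseform_map)))
    names(baseform_map) <- tolower(names(baseform_map))
  }
  if (length(compound_map)) {
    stopifnot(!is.null(names(compound_map)))
    names(compound_map) <- tolower(names(compound_map))
  }
  structure(list(baseform_map = baseform_map, compound_map = compound_map),
            class = "son_lexicon")
}

#' Read a lexicon from a tab-separated file
#'
#' Each line is `form<TAB>baseform[<TAB>part1|part2|...]`. Lines starting
#' with `#` and blank lines are skipped.
#'
#' @param path path to the lexicon file (UTF-8).
#' @return a [son_lexicon()].
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  base <- character()
  comp <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      stop("malformed lexicon line: '", ln, "'", call. = FALSE)
    base[[trimws(f[1])]] <- trimws(f[2])
    if (length(f) >= 3L && nzchar(trimws(f[3])))
      comp[[trimws(f[1])]] <- trimws(strsplit(f[3], "|", fixed = TRUE)[[1]])
  }
  son_lexicon(base, comp)
}

#' Load the bundled demonstration lexicon
#'
#' A small English/German lexicon (inflected forms to baseforms, a few
#' German compounds) used by the examples and tests.
#'
#' @return a [son_lexicon()].
#' @export
demo_lexicon <- function() {
  read_lexicon(system.file("extdata", "demo-lexicon.tsv", package = "sonq",
                           mustWork = TRUE))
}

TOKEN_REGEX <- "[\\p{L}\\p{N}]+(?:-[\\p{L}\\p{N}]+)*"

#' Tokenize a plain-text document
#'
#' @param text UTF-8 text; paragraphs are separated by blank lines.
#' @param lexicon a [son_lexicon()] supplying baseforms and compound parts.
#' @return an object of class `tokenized_document` whose `tokens` data
#'   frame has columns `surface`, `normalized`, `baseform`, `position`
#'   (0-based, strictly increasing), `sentence` and `paragraph` (0-based
#'   indices) plus a list column `compound_parts`.
#' @export
tokenize <- function(text, lexicon = son_lexicon()) {
  stopifnot(is.character(text), length(text) == 1L)
  paragraphs <- stringi::stri_split_regex(text, "(?:\r?\n)(?:[ \t]*\r?\n)+")[[1]]
  paragraphs <- paragraphs[nzchar(trimws(paragraphs))]

  surface <- character(0)
  sent_idx <- integer(0)
  para_idx <- integer(0)
  sent_counter <- 0L
  for (p in seq_along(paragraphs)) {
    sentences <- stringi::stri_split_regex(paragraphs[[p]],
                                           "(?<=[.!?])\\s+")[[1]]
    sentences <- sentences[nzchar(trimws(sentences))]
    for (s in sentences) {
      words <- stringi::stri_extract_all_regex(s, TOKEN_REGEX)[[1]]
      words <- words[!is.na(words)]
      if (length(words) == 0L) next
      surface <- c(surface, words)
      sent_idx <- c(sent_idx, rep(sent_counter, length(words)))
      para_idx <- c(para_idx, rep(p - 1L, length(words)))
      sent_counter <- sent_counter + 1L
    }
  }

  normalized <- if (length(surface)) normalize_text(surface) else character(0)
  key <- tolower(surface)
  baseform <- normalized
  parts <- rep(list(character(0)), length(surface))
  if (length(lexicon$baseform_map)) {
    hit <- match(key, names(lexicon$baseform_map))
    baseform[!is.na(hit)] <- unname(lexicon$baseform_map[hit[!is.na(hit)]])
  }
  if (length(lexicon$compound_map)) {
    hit <- match(key, names(lexicon$compound_map))
    for (i in which(!is.na(hit)))
      parts[[i]] <- lexicon$compound_map[[hit[i]]]
  }

  tokens <- data.frame(
    surface = surface, normalized = normalized, baseform = baseform,
    position = seq_along(surface) - 1L, sentence = sent_idx,
    paragraph = para_idx, stringsAsFactors = FALSE)
  tokens$compound_parts <- parts
  structure(list(tokens = tokens, text = text, lexicon = lexicon),
            class = "tokenized_document")
}

#' @export
print.tokenized_document <- function(x, ...) {
  cat("tokenized document: ", nrow(x$tokens), " tokens, ",
      length(unique(x$tokens$sentence)), " sentences, ",
      length(unique(x$tokens$paragraph)), " paragraphs\n", sep = "")
  invisible(x)
}
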