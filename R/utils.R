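# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize spreadsheet cell text to a concept identifier
#'
#' Trims the text, collapses internal whitespace runs to single underscores
#' and capitalizes the first letter of each whitespace-separated word, so
#' "endoscopic clipping system" becomes `Endoscopic_Clipping_System`.
#' Text that already is an identifier (no whitespace) is returned unchanged.
#'
#' @param x character vector of cell texts.
#' @return character vector of identifiers.
#' @export
normalize_identifier <- function(x) {
  vapply(x, function(s) {
    s <- trimws(s)
    if (!grepl("\\s", s)) return(s)
    words <- strsplit(s, "\\s+")[[1]]
    words <- vapply(words, function(w) {
      paste0(toupper(substr(w, 1, 1)), substr(w, 2, nchar(w)))
    }, character(1))
    paste(words, collapse = "_")
  }, character(1), USE.NAMES = FALSE)
}

is_identifier <- function(x) {
  length(x) == 1L && is.character(x) && nzchar(x) && !grepl("\\s", x)
}

# Case-fold + strip diacritics; the "D" term representation.
normalize_text <- function(x) {
  stringi::stri_trans_general(stringi::stri_trans_tolower(x), "Latin-ASCII")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Spreadsheet column index -> letters (1 -> A, 27 -> AA).
col_letter <- function(j) {
  s <- ""
  while (j > 0) {
    r <- (j - 1L) %% 26L
    s <- paste0(LETTERS[r + 1L], s)
    j <- (j - 1L) %/% 26L
  }
  s
}

# Canonical NEAR value: "S", "P" or a positive integer as string.
# Accepts "5", "NEAR/5", "S", "NEAR/S", case-insensitive prefix.
parse_near_value <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(NULL)
  v <- trimws(x)
  v <- sub("^NEAR/", "", v, ignore.case = TRUE)
  if (toupper(v) %in% c("S", "P")) return(toupper(v))
  if (grepl("^[0-9]+$", v) && as.integer(v) >= 1L) return(v)
  stop("invalid NEAR value: '", x, "' (expected positive integer, S or P)",
       call. = FALSE)
}

parse_mode_value <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(trimws(x))) return(NULL)
  v <- toupper(trimws(x))
  v <- sub("^MODE/", "", v)
  if (!v %in% c("E", "D", "B", "C"))
    stop("invalid MODE value: '", x, "' (expected E, D, B or C)", call. = FALSE)
  v
}
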