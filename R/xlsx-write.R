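# Minimal Office Open XML spreadsheet writer.
#
# Writes a workbook of text-only sheets (character matrices) as a .xlsx
# archive: shared-strings table, one worksheet part per sheet, workbook
# part, relationships and content types. All cell values are stored as
# shared strings; empty/NA cells are omitted. Scope is deliberately small:
# no styling, no formulas, no numeric cell types — the template format is
# purely textual.

write_xlsx_sheets <- function(sheets, path) {
  stopifnot(is.list(sheets), !is.null(names(sheets)), all(nzchar(names(sheets))))
  tmp <- tempfile("xlsx-")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)

  strings <- character(0)
  string_id <- new.env(parent = emptyenv())
  sid <- function(s) {
    key <- paste0("s", s)
    id <- string_id[[key]]
    if (is.null(id)) {
      strings[[length(strings) + 1L]] <<- s
      id <- length(strings) - 1L
      string_id[[key]] <- id
    }
    id
  }

  n <- length(sheets)
  for (i in seq_len(n)) {
    m <- sheets[[i]]
    if (is.null(m)) m <- matrix(character(0), nrow = 0, ncol = 0)
    rows <- character(0)
    for (r in seq_len(nrow(m))) {
      cells <- character(0)
      for (j in seq_len(ncol(m))) {
        v <- m[r, j]
        if (!is.na(v) && nzchar(v))
          cells <- c(cells, sprintf('<c r="%s%d" t="s"><v>%d</v></c>',
                                    col_letter(j), r, sid(v)))
      }
      if (length(cells))
        rows <- c(rows, sprintf('<row r="%d">%s</row>', r,
                                paste0(cells, collapse = "")))
    }
    part <- paste0(
      '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
      '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
      "<sheetData>", paste0(rows, collapse = ""), "</sheetData></worksheet>")
    writeLines(part, file.path(tmp, "xl", "worksheets",
                               sprintf("sheet%d.xml", i)), useBytes = TRUE)
  }

  sst <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    sprintf(paste0('<sst xmlns="http://schemas.openxmlformats.org/',
                   'spreadsheetml/2006/main" count="%d" uniqueCount="%d">'),
            length(strings), length(strings)),
    paste0(sprintf('<si><t xml:space="preserve">%s</t></si>',
                   xml_escape(strings)), collapse = ""),
    "</sst>")
  writeLines(sst, file.path(tmp, "xl", "sharedStrings.xml"), useBytes = TRUE)

  sheet_decls <- paste0(
    sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
            xml_escape(names(sheets)), seq_len(n), seq_len(n)),
    collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main"',
    ' xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<sheets>", sheet_decls, "</sheets></workbook>"),
    file.path(tmp, "xl", "workbook.xml"), useBytes = TRUE)

  rel_t <- "http://schemas.openxmlformats.org/officeDocument/2006/relationships"
  wb_rels <- c(
    sprintf('<Relationship Id="rId%d" Type="%s/worksheet" Target="worksheets/sheet%d.xml"/>',
            seq_len(n), rel_t, seq_len(n)),
    sprintf('<Relationship Id="rId%d" Type="%s/sharedStrings" Target="sharedStrings.xml"/>',
            n + 1L, rel_t))
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste0(wb_rels, collapse = ""), "</Relationships>"),
    file.path(tmp, "xl", "_rels", "workbook.xml.rels"), useBytes = TRUE)

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    sprintf('<Relationship Id="rId1" Type="%s/officeDocument" Target="xl/workbook.xml"/>',
            rel_t),
    "</Relationships>"),
    file.path(tmp, "_rels", ".rels"), useBytes = TRUE)

  ct <- "application/vnd.openxmlformats-officedocument.spreadsheetml"
  overrides <- paste0(
    sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="%s.worksheet+xml"/>',
            seq_len(n), ct), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    sprintf('<Override PartName="/xl/workbook.xml" ContentType="%s.sheet.main+xml"/>', ct),
    sprintf('<Override PartName="/xl/sharedStrings.xml" ContentType="%s.sharedStrings+xml"/>', ct),
    overrides, "</Types>"),
    file.path(tmp, "[Content_Types].xml"), useBytes = TRUE)

  if (file.exists(path)) unlink(path)
  zip::zip(normalizePath(path, mustWork = FALSE),
           files = c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
                     "xl/_rels/workbook.xml.rels", "xl/sharedStrings.xml",
                     sprintf("xl/worksheets/sheet%d.xml", seq_len(n))),
           root = tmp, mode = "mirror")
  invisible(path)
}
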