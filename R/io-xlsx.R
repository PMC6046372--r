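# Minimal XLSX (SpreadsheetML) writer: numeric cells stay numeric, strings go
# as inline strings, one worksheet per table. Output is byte-deterministic
# (fixed file timestamps before zipping) so repeated runs produce identical
# workbooks.

xlsx_col_letter <- function(j) {
  out <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    out <- paste0(LETTERS[r + 1], out)
    j <- (j - 1) %/% 26
  }
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xlsx_sheet_xml <- function(df) {
  nc <- ncol(df)
  rows <- character(nrow(df) + 1L)
  head_cells <- vapply(seq_len(nc), function(j) {
    sprintf('<c r="%s1" t="inlineStr"><is><t>%s</t></is></c>',
            xlsx_col_letter(j), xml_escape(names(df)[j]))
  }, character(1))
  rows[1] <- paste0('<row r="1">', paste(head_cells, collapse = ""), "</row>")
  is_num <- vapply(df, is.numeric, logical(1))
  for (i in seq_len(nrow(df))) {
    cells <- character(nc)
    for (j in seq_len(nc)) {
      v <- df[[j]][i]
      ref <- paste0(xlsx_col_letter(j), i + 1L)
      cells[j] <- if (is.na(v)) {
        sprintf('<c r="%s"/>', ref)
      } else if (is_num[j]) {
        sprintf('<c r="%s"><v>%.17g</v></c>', ref, as.numeric(v))
      } else {
        sprintf('<c r="%s" t="inlineStr"><is><t>%s</t></is></c>',
                ref, xml_escape(as.character(v)))
      }
    }
    rows[i + 1L] <- paste0(sprintf('<row r="%d">', i + 1L),
                           paste(cells, collapse = ""), "</row>")
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         "<sheetData>", paste(rows, collapse = ""), "</sheetData></worksheet>")
}

#' Write data frames to a spreadsheet, one sheet per table
#'
#' @param sheets named list of data frames.
#' @param path output `.xlsx` file.
#' @return `path`, invisibly.
#' @export
write_xlsx_sheets <- function(sheets, path) {
  stopifnot(is.list(sheets), length(sheets) >= 1L)
  if (is.null(names(sheets)) || any(!nzchar(names(sheets))))
    stop("every sheet needs a name")
  tmp <- tempfile("xlsx")
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)

  n <- length(sheets)
  ct_sheets <- paste(sprintf(
    '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    ct_sheets, "</Types>"),
    file.path(tmp, "[Content_Types].xml"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    "</Relationships>"),
    file.path(tmp, "_rels", ".rels"))

  sheet_tags <- paste(sprintf(
    '<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
    xml_escape(names(sheets)), seq_len(n), seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    "<sheets>", sheet_tags, "</sheets></workbook>"),
    file.path(tmp, "xl", "workbook.xml"))

  rel_tags <- paste(sprintf(
    '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
    seq_len(n), seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    rel_tags, "</Relationships>"),
    file.path(tmp, "xl", "_rels", "workbook.xml.rels"))

  for (k in seq_len(n)) {
    writeLines(xlsx_sheet_xml(as.data.frame(sheets[[k]])),
               file.path(tmp, "xl", "worksheets", sprintf("sheet%d.xml", k)))
  }

  files <- c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
             "xl/_rels/workbook.xml.rels",
             file.path("xl", "worksheets", sprintf("sheet%d.xml", seq_len(n))))
  # pin timestamps so the archive is byte-identical across runs
  for (f in c(files, "_rels", "xl", "xl/_rels", "xl/worksheets"))
    Sys.setFileTime(file.path(tmp, f), as.POSIXct("2020-01-01", tz = "UTC"))
  if (file.exists(path)) unlink(path)
  zip::zip(normalizePath(path, mustWork = FALSE), files, root = tmp,
           include_directories = FALSE)
  invisible(path)
}
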