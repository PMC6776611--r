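# Minimal xlsx (SpreadsheetML) writer/reader for the tabular dialect.
# Written cells are inline strings; fills come from a per-cell color matrix.
# The reader also understands shared strings so that workbooks edited or
# produced by common spreadsheet tools can be loaded back.

.colLetter <- function(j) {
  s <- ""
  while (j > 0) {
    r <- (j - 1) %% 26
    s <- paste0(LETTERS[r + 1], s)
    j <- (j - 1) %/% 26
  }
  s
}

.cellRef <- function(i, j) paste0(.colLetter(j), i)

.refToCol <- function(ref) {
  letters <- gsub("[0-9]+$", "", ref)
  chars <- strsplit(letters, "")[[1]]
  Reduce(function(acc, ch) acc * 26L + (utf8ToInt(ch) - 64L), chars, 0L)
}

.refToRow <- function(ref) as.integer(gsub("^[A-Z]+", "", ref))

.stylesXml <- function(colors) {
  fills <- paste0(
    '<fill><patternFill patternType="none"/></fill>',
    '<fill><patternFill patternType="gray125"/></fill>',
    paste(vapply(colors, function(cl) sprintf(
      '<fill><patternFill patternType="solid"><fgColor rgb="FF%s"/><bgColor indexed="64"/></patternFill></fill>',
      toupper(cl)
    ), ""), collapse = "")
  )
  xfs <- paste0(
    '<xf numFmtId="0" fontId="0" fillId="0" borderId="0" xfId="0"/>',
    paste(vapply(seq_along(colors), function(k) sprintf(
      '<xf numFmtId="0" fontId="0" fillId="%d" borderId="0" xfId="0" applyFill="1"/>',
      k + 1L
    ), ""), collapse = "")
  )
  paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<styleSheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<fonts count="1"><font><sz val="11"/><name val="Calibri"/></font></fonts>',
    sprintf('<fills count="%d">%s</fills>', length(colors) + 2L, fills),
    '<borders count="1"><border><left/><right/><top/><bottom/><diagonal/></border></borders>',
    '<cellStyleXfs count="1"><xf numFmtId="0" fontId="0" fillId="0" borderId="0"/></cellStyleXfs>',
    sprintf('<cellXfs count="%d">%s</cellXfs>', length(colors) + 1L, xfs),
    '</styleSheet>'
  )
}

# grid: character matrix (NA = absent cell); fills: NULL or character matrix
# of RRGGBB colors (NA = no fill), same shape as grid.
.xlsxWriteGrid <- function(grid, path, fills = NULL) {
  colors <- if (is.null(fills)) character(0) else {
    unique(stats::na.omit(as.vector(fills)))
  }
  styleOf <- function(i, j) {
    if (is.null(fills) || is.na(fills[i, j])) 0L
    else match(fills[i, j], colors)
  }
  rowsXml <- character(0)
  if (nrow(grid) > 0) {
    rowsXml <- vapply(seq_len(nrow(grid)), function(i) {
      cells <- character(0)
      for (j in seq_len(ncol(grid))) {
        v <- grid[i, j]
        s <- styleOf(i, j)
        if (is.na(v) && s == 0L) next
        cells <- c(cells, if (is.na(v)) {
          sprintf('<c r="%s" s="%d"/>', .cellRef(i, j), s)
        } else {
          sprintf(
            '<c r="%s" s="%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
            .cellRef(i, j), s, xmlEscape(v)
          )
        })
      }
      sprintf('<row r="%d">%s</row>', i, paste(cells, collapse = ""))
    }, "")
  }
  sheet <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<sheetData>', paste(rowsXml, collapse = ""), '</sheetData></worksheet>'
  )
  tmp <- tempfile("xlsx")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  wr <- function(rel, text) writeLines(text, file.path(tmp, rel), useBytes = TRUE)
  wr("[Content_Types].xml", paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/worksheets/sheet1.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
    '</Types>'
  ))
  wr(file.path("_rels", ".rels"), paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'
  ))
  wr(file.path("xl", "workbook.xml"), paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets><sheet name="Sheet1" sheetId="1" r:id="rId1"/></sheets></workbook>'
  ))
  wr(file.path("xl", "_rels", "workbook.xml.rels"), paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet1.xml"/>',
    '<Relationship Id="rId2" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/styles" Target="styles.xml"/>',
    '</Relationships>'
  ))
  wr(file.path("xl", "styles.xml"), .stylesXml(colors))
  wr(file.path("xl", "worksheets", "sheet1.xml"), sheet)
  if (file.exists(path)) unlink(path)
  zip::zip(
    zipfile = file.path(normalizePath(dirname(path)), basename(path)),
    files = c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
              "xl/_rels/workbook.xml.rels", "xl/styles.xml",
              "xl/worksheets/sheet1.xml"),
    root = tmp, mode = "mirror"
  )
  unlink(tmp, recursive = TRUE)
  invisible(path)
}

# Returns a character matrix ("" for empty cells). Styling is ignored.
.xlsxReadGrid <- function(path) {
  if (!file.exists(path)) odmlStop("odmlIoError", "file not found: %s", path)
  tmp <- tempfile("xlsxr")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  zip::unzip(path, exdir = tmp)
  ns <- c(m = "http://schemas.openxmlformats.org/spreadsheetml/2006/main")
  # locate the first worksheet via the workbook relationships
  relPath <- file.path(tmp, "xl", "_rels", "workbook.xml.rels")
  sheetFile <- file.path(tmp, "xl", "worksheets", "sheet1.xml")
  if (file.exists(relPath)) {
    rels <- xml2::read_xml(relPath)
    targets <- xml2::xml_find_all(
      rels, ".//*[local-name()='Relationship']"
    )
    types <- xml2::xml_attr(targets, "Type")
    ws <- which(grepl("/worksheet$", types))
    if (length(ws)) {
      tgt <- xml2::xml_attr(targets[[ws[1]]], "Target")
      tgt <- sub("^/", "", tgt)
      cand <- if (startsWith(tgt, "xl/")) file.path(tmp, tgt) else
        file.path(tmp, "xl", tgt)
      if (file.exists(cand)) sheetFile <- cand
    }
  }
  if (!file.exists(sheetFile)) {
    odmlStop("odmlParseError", "no worksheet found in %s", path)
  }
  shared <- character(0)
  ssFile <- file.path(tmp, "xl", "sharedStrings.xml")
  if (file.exists(ssFile)) {
    ss <- xml2::read_xml(ssFile)
    shared <- vapply(
      xml2::xml_find_all(ss, ".//*[local-name()='si']"),
      xml2::xml_text, ""
    )
  }
  sheet <- xml2::read_xml(sheetFile)
  cells <- xml2::xml_find_all(sheet, ".//*[local-name()='c']")
  if (!length(cells)) {
    return(matrix(character(0), nrow = 0, ncol = 0))
  }
  refs <- xml2::xml_attr(cells, "r")
  rowsIdx <- vapply(refs, .refToRow, 0L)
  colsIdx <- vapply(refs, .refToCol, 0L)
  types <- xml2::xml_attr(cells, "t")
  vals <- vapply(seq_along(cells), function(k) {
    cell <- cells[[k]]
    t <- types[k]
    if (!is.na(t) && t == "inlineStr") {
      xml2::xml_text(xml2::xml_find_first(cell, ".//*[local-name()='is']"))
    } else {
      v <- xml2::xml_find_first(cell, ".//*[local-name()='v']")
      if (inherits(v, "xml_missing")) "" else {
        txt <- xml2::xml_text(v)
        if (!is.na(t) && t == "s") {
          shared[as.integer(txt) + 1L]
        } else if (!is.na(t) && t == "b") {
          if (identical(txt, "1")) "True" else "False"
        } else txt
      }
    }
  }, "")
  grid <- matrix("", nrow = max(rowsIdx), ncol = max(colsIdx))
  for (k in seq_along(vals)) {
    grid[rowsIdx[k], colsIdx[k]] <- if (is.na(vals[k])) "" else vals[k]
  }
  grid
}
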