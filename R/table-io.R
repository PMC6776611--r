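# csv/xlsx serialization of the flat dialect: document-attribute top row,
# header row (customizable via a layout), one line per flat row.

#' Canonical display headers of the flat dialect
#'
#' @return Named character vector mapping canonical column keys to the
#'   default display headers (\code{"Path to Section"},
#'   \code{"Property Name"}, \code{"odML Data Type"}, ...).
#' @export
canonicalHeaders <- function() {
  c(
    path_to_section = "Path to Section",
    section_name = "Section Name",
    section_type = "Section Type",
    section_definition = "Section Definition",
    property_name = "Property Name",
    property_definition = "Property Definition",
    value = "Value",
    data_unit = "Data Unit",
    data_uncertainty = "Data Uncertainty",
    odml_data_type = "odML Data Type",
    value_origin = "Value Origin",
    property_reference = "Property Reference"
  )
}

#' Create a style specification
#'
#' @param sectionRowColors Two alternating fills (hex \code{RRGGBB}) keyed
#'   to section changes.
#' @param propertyRowColors Two alternating fills keyed to property changes.
#' @param defaultValueFill Fill for value cells equal to the registry
#'   default of their data type (light yellow by default).
#' @param missingValueFill Fill for empty value cells (red by default).
#' @param headerFill Fill for the header row.
#' @return A \linkS4class{StyleSpec}.
#' @export
styleSpec <- function(sectionRowColors = c("B7CCE4", "D9E2F0"),
                      propertyRowColors = c("D9D9D9", "F2F2F2"),
                      defaultValueFill = "FFFF99",
                      missingValueFill = "FF0000",
                      headerFill = "8DB4E2") {
  new("StyleSpec",
    sectionRowColors = sectionRowColors,
    propertyRowColors = propertyRowColors,
    defaultValueFill = defaultValueFill,
    missingValueFill = missingValueFill,
    headerFill = headerFill
  )
}

#' Create a table layout
#'
#' @param columns Ordered canonical column keys (see
#'   \code{\link{flatColumns}}); must include \code{path_to_section},
#'   \code{property_name} and \code{value}.
#' @param headerMap Named character vector mapping canonical keys to
#'   display headers; defaults to \code{\link{canonicalHeaders}}. Partial
#'   maps are completed with the canonical headers.
#' @param compaction Blank cells identical to the cell above on write.
#' @param style A \linkS4class{StyleSpec} for xlsx output, or \code{NULL}.
#' @return A \linkS4class{TableLayout}.
#' @examples
#' lay <- tableLayout(
#'   columns = c("path_to_section", "property_name", "value", "data_unit"),
#'   headerMap = c(path_to_section = "Section", property_name = "Measure",
#'                 data_unit = "Unit")
#' )
#' @export
tableLayout <- function(columns = flatColumns(),
                        headerMap = canonicalHeaders(),
                        compaction = FALSE, style = NULL) {
  hm <- canonicalHeaders()
  hm[names(headerMap)] <- headerMap
  unknown <- setdiff(columns, names(hm))
  if (length(unknown)) {
    odmlStop("odmlLayoutError", "unknown column key(s): %s",
             paste(unknown, collapse = ", "))
  }
  new("TableLayout",
    columns = columns,
    headerMap = hm,
    compaction = isTRUE(compaction),
    style = if (is.null(style)) list() else list(style)
  )
}

.layoutStyle <- function(layout) {
  if (length(layout@style)) layout@style[[1]] else NULL
}

# Shared grid builder for csv and xlsx. Returns the document row, the
# header row, the body matrix and per-cell styling metadata.
.buildGrid <- function(document, layout, registry = dtypeRegistry()) {
  validObject(layout)
  flat <- flattenDocument(document, registry)
  rows <- flat$rows
  docRow <- c(
    "Document Information",
    "author", orNA(flat$info$author),
    "date", orNA(flat$info$date),
    "version", orNA(flat$info$version),
    "repository", orNA(flat$info$repository)
  )
  header <- unname(layout@headerMap[layout@columns])
  n <- nrow(rows)
  # style keys computed on the uncompacted rows
  secIdx <- if (n) {
    cumsum(c(TRUE, rows$path_to_section[-1] != rows$path_to_section[-n]))
  } else integer(0)
  propKey <- if (n) paste(rows$path_to_section, rows$property_name) else character(0)
  propIdx <- if (n) cumsum(c(TRUE, propKey[-1] != propKey[-n])) else integer(0)
  isMissing <- if (n) is.na(rows$value) else logical(0)
  isDefault <- logical(n)
  if (n) {
    for (i in seq_len(n)) {
      dt <- rows$odml_data_type[i]
      if (!is.na(rows$value[i]) && !is.na(dt)) {
        def <- formatValue(defaultValue(dt, registry), dt, registry)
        cell <- rows$value[i]
        if (identical(cell, .EMPTY_STRING_SENTINEL)) cell <- ""
        isDefault[i] <- identical(cell, def)
      }
    }
  }
  outRows <- if (isTRUE(layout@compaction)) compactRows(rows) else rows
  body <- as.matrix(outRows[, layout@columns, drop = FALSE])
  dimnames(body) <- NULL
  list(
    docRow = docRow, header = header, body = body,
    secIdx = secIdx, propIdx = propIdx,
    isMissing = isMissing, isDefault = isDefault
  )
}

#' Write a document as a csv table
#'
#' Writes the RFC 4180 rendering of the flat dialect: line 1 holds the
#' document attributes (\code{"Document Information"} followed by
#' \code{author}/\code{date}/\code{version}/\code{repository} key-value
#' cells), line 2 the display headers per the layout, then one line per
#' flat row (compacted when the layout says so). Any style in the layout is
#' ignored: csv carries no formatting.
#'
#' @param document An \linkS4class{odmlDocument}.
#' @param path Output file.
#' @param layout A \linkS4class{TableLayout}.
#' @param registry Data-type registry.
#' @return Invisibly, \code{path}.
#' @export
writeOdmlCsv <- function(document, path, layout = tableLayout(),
                         registry = dtypeRegistry()) {
  g <- .buildGrid(document, layout, registry)
  ncol <- max(length(g$docRow), length(g$header))
  pad <- function(x) {
    x[is.na(x)] <- ""
    c(x, rep("", ncol - length(x)))
  }
  m <- rbind(pad(g$docRow), pad(g$header))
  if (nrow(g$body)) {
    m <- rbind(m, t(apply(g$body, 1, pad)))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(
    m, con, sep = ",", quote = TRUE, row.names = FALSE, col.names = FALSE,
    eol = "\n", fileEncoding = "UTF-8", qmethod = "double"
  )
  invisible(path)
}

.parseDocRow <- function(cells) {
  if (length(cells) == 0 || !identical(cells[1], "Document Information")) {
    odmlStop("odmlDialectError",
             "first row must start with 'Document Information'")
  }
  info <- list()
  k <- 2L
  while (k < length(cells)) {
    key <- cells[k]
    val <- if (k + 1L <= length(cells)) cells[k + 1L] else ""
    if (nzchar(key)) {
      if (!key %in% c("author", "date", "version", "repository")) {
        odmlStop("odmlDialectError",
                 "unknown document attribute '%s' in the top row", key)
      }
      info[[key]] <- if (nzchar(val)) val else NULL
    }
    k <- k + 2L
  }
  info
}

.resolveHeaders <- function(display, layout) {
  hm <- layout@headerMap
  inv <- stats::setNames(names(hm), unname(hm))
  nz <- nzchar(display)
  unmatched <- setdiff(display[nz], names(inv))
  if (length(unmatched)) {
    odmlStop("odmlHeaderError",
             "unknown column header(s): %s (provide a matching layout)",
             paste(unmatched, collapse = ", "))
  }
  keys <- rep(NA_character_, length(display))
  keys[nz] <- unname(inv[display[nz]])
  keys
}

.gridToDocument <- function(grid, layout, registry) {
  if (nrow(grid) < 2) {
    odmlStop("odmlDialectError",
             "table must contain a document row and a header row")
  }
  info <- .parseDocRow(grid[1, ])
  keys <- .resolveHeaders(grid[2, ], layout)
  rows <- .emptyRows(max(0L, nrow(grid) - 2L))
  if (nrow(grid) > 2) {
    for (j in seq_along(keys)) {
      if (is.na(keys[j])) next
      cells <- grid[3:nrow(grid), j]
      cells[cells == ""] <- NA_character_
      rows[[keys[j]]] <- cells
    }
  }
  unflattenDocument(info, expandRows(rows), registry)
}

#' Read a csv table back into a document
#'
#' Columns are associated with odML attributes by header name, so column
#' order in the file is free. Custom display headers used at write time
#' must be supplied again via the layout. The rows are expanded
#' (\code{\link{expandRows}}) and rebuilt with
#' \code{\link{unflattenDocument}}.
#'
#' @param path csv file in the dialect.
#' @param layout A \linkS4class{TableLayout} carrying the header map used
#'   at write time.
#' @param registry Data-type registry.
#' @return An \linkS4class{odmlDocument}.
#' @export
readOdmlCsv <- function(path, layout = tableLayout(),
                        registry = dtypeRegistry()) {
  if (!file.exists(path)) odmlStop("odmlIoError", "file not found: %s", path)
  raw <- utils::read.csv(
    path, header = FALSE, colClasses = "character",
    fileEncoding = "UTF-8", blank.lines.skip = FALSE,
    stringsAsFactors = FALSE, fill = TRUE
  )
  grid <- as.matrix(raw)
  dimnames(grid) <- NULL
  .gridToDocument(grid, layout, registry)
}

#' Write a document as an xlsx workbook
#'
#' One worksheet with the same logical grid as the csv rendering. When the
#' layout carries a \linkS4class{StyleSpec}, fills are applied: alternating
#' section/property block colors, a highlight for value cells holding the
#' registry default of their type, and a (red) highlight for empty value
#' cells. Styling is presentation only and never affects reading.
#'
#' @inheritParams writeOdmlCsv
#' @return Invisibly, \code{path}.
#' @export
writeOdmlXlsx <- function(document, path, layout = tableLayout(),
                          registry = dtypeRegistry()) {
  g <- .buildGrid(document, layout, registry)
  ncol <- max(length(g$docRow), length(g$header))
  pad <- function(x) c(x, rep(NA_character_, ncol - length(x)))
  grid <- rbind(pad(g$docRow), pad(g$header))
  if (nrow(g$body)) {
    grid <- rbind(grid, t(apply(g$body, 1, pad)))
  }
  style <- .layoutStyle(layout)
  fills <- NULL
  if (!is.null(style)) {
    fills <- matrix(NA_character_, nrow = nrow(grid), ncol = ncol)
    fills[2, seq_along(g$header)] <- style@headerFill
    if (nrow(g$body)) {
      secCols <- which(layout@columns %in% .SECTION_GROUP)
      propCols <- which(layout@columns %in% .PROPERTY_GROUP)
      valCol <- which(layout@columns == "value")
      for (i in seq_len(nrow(g$body))) {
        r <- i + 2L
        fills[r, secCols] <-
          style@sectionRowColors[(g$secIdx[i] - 1L) %% 2L + 1L]
        fills[r, propCols] <-
          style@propertyRowColors[(g$propIdx[i] - 1L) %% 2L + 1L]
        if (g$isMissing[i]) {
          fills[r, valCol] <- style@missingValueFill
        } else if (g$isDefault[i]) {
          fills[r, valCol] <- style@defaultValueFill
        }
      }
    }
  }
  .xlsxWriteGrid(grid, path, fills)
  invisible(path)
}

#' Read an xlsx table back into a document
#'
#' Identical contract to \code{\link{readOdmlCsv}}; all cell styling
#' (including arbitrary user coloring) is ignored.
#'
#' @inheritParams readOdmlCsv
#' @param path xlsx file in the dialect.
#' @return An \linkS4class{odmlDocument}.
#' @export
readOdmlXlsx <- function(path, layout = tableLayout(),
                         registry = dtypeRegistry()) {
  grid <- .xlsxReadGrid(path)
  .gridToDocument(grid, layout, registry)
}

#' Persist a table layout as a plain-text config
#'
#' Key-value format: \code{compaction=true|false} plus one ordered
#' \code{column=<key>=<display header>} line per selected column. Styles
#' are not persisted. \code{\link{readLayoutConfig}} restores the layout.
#'
#' @param layout A \linkS4class{TableLayout}.
#' @param path Output file.
#' @return Invisibly, \code{path}.
#' @export
writeLayoutConfig <- function(layout, path) {
  lines <- c(
    sprintf("compaction=%s", if (layout@compaction) "true" else "false"),
    sprintf("column=%s=%s", layout@columns,
            unname(layout@headerMap[layout@columns]))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeLayoutConfig
#' @return For \code{readLayoutConfig}, the restored
#'   \linkS4class{TableLayout}.
#' @export
readLayoutConfig <- function(path) {
  if (!file.exists(path)) odmlStop("odmlIoError", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  compaction <- FALSE
  cols <- character(0)
  hm <- character(0)
  for (ln in lines) {
    if (startsWith(ln, "compaction=")) {
      compaction <- identical(sub("^compaction=", "", ln), "true")
    } else if (startsWith(ln, "column=")) {
      rest <- sub("^column=", "", ln)
      eq <- regexpr("=", rest, fixed = TRUE)
      if (eq < 0) {
        odmlStop("odmlLayoutError", "malformed column line: %s", ln)
      }
      key <- substr(rest, 1, eq - 1)
      disp <- substr(rest, eq + 1, nchar(rest))
      cols <- c(cols, key)
      hm[key] <- disp
    } else {
      odmlStop("odmlLayoutError", "unknown config line: %s", ln)
    }
  }
  tableLayout(columns = cols, headerMap = hm, compaction = compaction)
}
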