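# Conversion between the document tree and the flat row representation:
# one row per value, section hierarchy encoded in a "/"-joined path column.

#' Canonical column keys of the flat dialect
#'
#' @return Character vector of the canonical column keys, in default order.
#' @export
flatColumns <- function() {
  c(
    "path_to_section", "section_name", "section_type", "section_definition",
    "property_name", "property_definition", "value", "data_unit",
    "data_uncertainty", "odml_data_type", "value_origin", "property_reference"
  )
}

.SECTION_GROUP <- c(
  "path_to_section", "section_name", "section_type", "section_definition"
)
.PROPERTY_GROUP <- c(
  "property_name", "property_definition", "data_unit", "data_uncertainty",
  "odml_data_type", "value_origin", "property_reference"
)

# Empty-string values are rendered as a literal quote pair so that an empty
# cell can keep meaning "no value".
.EMPTY_STRING_SENTINEL <- "\"\""

.renderValue <- function(v, dtype, registry) {
  s <- formatValue(v, if (length(dtype)) dtype else NULL, registry)
  if (identical(s, "")) .EMPTY_STRING_SENTINEL else s
}

.emptyRows <- function(n = 0) {
  cols <- flatColumns()
  df <- as.data.frame(
    stats::setNames(rep(list(rep(NA_character_, n)), length(cols)), cols),
    stringsAsFactors = FALSE
  )
  df
}

#' Flatten a document to rows
#'
#' Produces exactly one row per value in depth-first document order
#' (properties of a section before its subsections). A property with an
#' empty value list yields a single row with an empty value cell. Sections
#' whose subtree holds no properties yield no rows: the dialect has no
#' section-only row, which is its one declared loss.
#'
#' @param document An \linkS4class{odmlDocument}; must pass
#'   \code{\link{validateDocument}}.
#' @param registry Data-type registry used for value rendering.
#' @return A list with elements \code{info} (named list of the document
#'   attributes \code{author}, \code{date}, \code{version},
#'   \code{repository}) and \code{rows} (data frame with the
#'   \code{\link{flatColumns}} columns, \code{NA} for absent cells).
#' @seealso \code{\link{unflattenDocument}}, \code{\link{compactRows}}
#' @export
flattenDocument <- function(document, registry = dtypeRegistry()) {
  .stopIfInvalid(document, registry)
  rows <- list()
  emit <- function(sec, path, prop) {
    base <- c(
      path_to_section = path,
      section_name = sec@name,
      section_type = orNA(sec@type),
      section_definition = orNA(sec@definition),
      property_name = prop@name,
      property_definition = orNA(prop@definition),
      value = NA_character_,
      data_unit = orNA(prop@unit),
      data_uncertainty = if (length(prop@uncertainty)) {
        formatValue(prop@uncertainty, "float", registry)
      } else NA_character_,
      odml_data_type = orNA(prop@dtype),
      value_origin = orNA(prop@valueOrigin),
      property_reference = orNA(prop@reference)
    )
    if (length(prop@values) == 0) {
      rows[[length(rows) + 1L]] <<- base
    } else {
      for (v in prop@values) {
        r <- base
        r[["value"]] <- .renderValue(v, prop@dtype, registry)
        rows[[length(rows) + 1L]] <<- r
      }
    }
  }
  walk <- function(sec, parent) {
    path <- paste0(parent, "/", sec@name)
    for (p in sec@properties) emit(sec, path, p)
    for (sub in sec@sections) walk(sub, path)
  }
  for (s in document@sections) walk(s, "")
  df <- if (length(rows)) {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  } else {
    .emptyRows(0)
  }
  rownames(df) <- NULL
  list(
    info = list(
      author = document@author, date = document@date,
      version = document@version, repository = document@repository
    ),
    rows = df
  )
}

.cellSame <- function(a, b) {
  (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
}

#' Compact repeated cells
#'
#' For readability, a cell identical to the cell above within its column
#' group is blanked (\code{NA}): the section-level columns blank while the
#' path is unchanged, the property-level columns additionally require the
#' property name to be unchanged. A change of section resets blanking for
#' all property-level columns. Value cells are never blanked. The number of
#' rows never changes; \code{\link{expandRows}} is the exact inverse.
#'
#' @param rows Data frame of rows as produced by
#'   \code{\link{flattenDocument}}.
#' @return Data frame of the same shape with repeated cells set to
#'   \code{NA}.
#' @export
compactRows <- function(rows) {
  out <- rows
  n <- nrow(rows)
  if (n < 2) return(out)
  secCols <- intersect(.SECTION_GROUP, names(rows))
  propCols <- intersect(.PROPERTY_GROUP, names(rows))
  for (i in 2:n) {
    sameSec <- .cellSame(rows$path_to_section[i], rows$path_to_section[i - 1])
    if (!sameSec) next
    for (col in secCols) {
      if (.cellSame(rows[[col]][i], rows[[col]][i - 1])) {
        out[[col]][i] <- NA_character_
      }
    }
    sameProp <- .cellSame(rows$property_name[i], rows$property_name[i - 1])
    if (!sameProp) next
    for (col in propCols) {
      if (.cellSame(rows[[col]][i], rows[[col]][i - 1])) {
        out[[col]][i] <- NA_character_
      }
    }
  }
  out
}

#' Expand compacted rows
#'
#' Inverse of \code{\link{compactRows}}: blanked cells are forward-filled
#' from the nearest row above, respecting the reset rule — section-level
#' cells fill only while the path cell is blank (same section), and
#' property-level cells fill only while the property-name cell is also
#' blank (same property). A blank path or property name in the first row is
#' a dialect error.
#'
#' @param rows Data frame of (possibly) compacted rows.
#' @return Data frame with all blanks resolved.
#' @export
expandRows <- function(rows) {
  out <- rows
  n <- nrow(rows)
  if (n == 0) return(out)
  if (is.na(rows$path_to_section[1]) || is.na(rows$property_name[1])) {
    odmlStop("odmlDialectError",
             "first table row has a blank path or property name")
  }
  secCols <- intersect(.SECTION_GROUP, names(rows))
  propCols <- intersect(.PROPERTY_GROUP, names(rows))
  if (n < 2) return(out)
  for (i in 2:n) {
    sameSec <- is.na(rows$path_to_section[i])
    if (!sameSec) next
    for (col in secCols) {
      if (is.na(out[[col]][i])) out[[col]][i] <- out[[col]][i - 1]
    }
    sameProp <- is.na(rows$property_name[i])
    if (!sameProp) next
    for (col in propCols) {
      if (is.na(out[[col]][i])) out[[col]][i] <- out[[col]][i - 1]
    }
  }
  out
}

.parseCellValue <- function(cell, dtype, registry) {
  if (identical(cell, .EMPTY_STRING_SENTINEL)) {
    if (length(dtype) == 0 ||
        dtype %in% c("string", "text", "url", "person")) {
      return("")
    }
    odmlStop("odmlCoerceError",
             "empty-string sentinel is not valid for dtype '%s'", dtype)
  }
  if (length(dtype) == 0) return(cell)
  coerceValue(cell, dtype, registry)
}

#' Rebuild a document from flat rows
#'
#' Consecutive rows sharing (path, property name) form one property whose
#' value list preserves row order; intermediate sections implied by the
#' path are created with empty attributes. Non-consecutive reappearance of
#' a (path, property) pair is a dialect error; conflicting property-level
#' cells within one group are a consistency error naming the rows. UUIDs
#' are not represented in the dialect, so all entities receive fresh ones.
#'
#' @param info Named list of document attributes (as returned by
#'   \code{\link{flattenDocument}}); may be \code{NULL}.
#' @param rows Data frame of expanded rows.
#' @param registry Data-type registry for value coercion.
#' @return An \linkS4class{odmlDocument}.
#' @export
unflattenDocument <- function(info, rows, registry = dtypeRegistry()) {
  if (is.null(info)) info <- list()
  n <- nrow(rows)
  for (col in setdiff(flatColumns(), names(rows))) {
    rows[[col]] <- rep(NA_character_, n)
  }
  root <- new.env(parent = emptyenv())
  root$children <- list()     # named list of nodes, insertion-ordered
  newNode <- function(name) {
    e <- new.env(parent = emptyenv())
    e$name <- name
    e$type <- NA_character_
    e$definition <- NA_character_
    e$props <- list()
    e$children <- list()
    e
  }
  if (n > 0) {
    key <- paste(rows$path_to_section, rows$property_name, sep = "\r")
    if (anyNA(rows$path_to_section) || anyNA(rows$property_name)) {
      odmlStop("odmlDialectError",
               "rows contain blank path or property-name cells; expand first")
    }
    runs <- rle(key)
    if (anyDuplicated(runs$values)) {
      dup <- runs$values[duplicated(runs$values)][1]
      odmlStop("odmlDialectError",
               "rows of one property are not consecutive: %s",
               gsub("\r", ":", dup, fixed = TRUE))
    }
    groupId <- rep(seq_along(runs$lengths), runs$lengths)
    for (g in seq_along(runs$lengths)) {
      idx <- which(groupId == g)
      grp <- rows[idx, , drop = FALSE]
      for (col in c(.SECTION_GROUP, setdiff(.PROPERTY_GROUP, "property_name"))) {
        cells <- grp[[col]]
        ok <- all(vapply(cells, .cellSame, logical(1), b = cells[1]))
        if (!ok) {
          odmlStop("odmlConsistencyError",
                   "rows %s disagree on '%s' within property '%s'",
                   paste(idx, collapse = ", "), col, grp$property_name[1])
        }
      }
      path <- grp$path_to_section[1]
      if (!startsWith(path, "/")) {
        odmlStop("odmlDialectError", "section path '%s' must start with '/'",
                 path)
      }
      parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
      node <- root
      for (part in parts) {
        if (is.null(node$children[[part]])) {
          node$children[[part]] <- newNode(part)
        }
        node <- node$children[[part]]
      }
      secName <- grp$section_name[1]
      if (!is.na(secName) && secName != node$name) {
        odmlStop("odmlConsistencyError",
                 "section name '%s' does not match last path component '%s'",
                 secName, node$name)
      }
      for (fld in c("type", "definition")) {
        cell <- grp[[paste0("section_", fld)]][1]
        if (!is.na(cell)) {
          if (!is.na(node[[fld]]) && node[[fld]] != cell) {
            odmlStop("odmlConsistencyError",
                     "conflicting section %s for path '%s'", fld, path)
          }
          node[[fld]] <- cell
        }
      }
      dt <- grp$odml_data_type[1]
      dt <- if (is.na(dt)) character(0) else resolveDtype(dt, registry)
      vals <- list()
      for (cell in grp$value) {
        if (!is.na(cell)) {
          vals[[length(vals) + 1L]] <- .parseCellValue(cell, dt, registry)
        }
      }
      unc <- grp$data_uncertainty[1]
      node$props[[length(node$props) + 1L]] <- odmlProperty(
        name = grp$property_name[1],
        definition = cellToSlot(grp$property_definition[1]),
        values = vals,
        dtype = if (length(dt)) dt else NULL,
        unit = cellToSlot(grp$data_unit[1]),
        uncertainty = if (!is.na(unc)) as.numeric(unc) else NULL,
        valueOrigin = cellToSlot(grp$value_origin[1]),
        reference = cellToSlot(grp$property_reference[1]),
        registry = registry
      )
    }
  }
  buildSection <- function(node) {
    odmlSection(
      name = node$name,
      type = cellToSlot(node$type),
      definition = cellToSlot(node$definition),
      properties = node$props,
      sections = lapply(unname(node$children), buildSection)
    )
  }
  doc <- odmlDocument(
    author = cellToSlot(orNA(info$author)),
    date = cellToSlot(orNA(info$date)),
    version = cellToSlot(orNA(info$version)),
    repository = cellToSlot(orNA(info$repository)),
    sections = lapply(unname(root$children), buildSection)
  )
  .stopIfInvalid(doc, registry)
  doc
}
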