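#' @import methods
NULL

#' odML property: an extended key-value pair
#'
#' A Property is the leaf entity of an odML tree. It carries a name and an
#' ordered list of values that share one set of value-level attributes: the
#' data type (\code{dtype}), physical \code{unit} and measurement
#' \code{uncertainty}, plus provenance fields (\code{valueOrigin},
#' \code{reference}). All values of one property must conform to its dtype;
#' heterogeneous value lists are a modelling error.
#'
#' Scalar attributes that are absent are stored as length-zero vectors.
#'
#' @slot name Property name (non-empty, no \code{"/"}).
#' @slot definition Optional free-text definition.
#' @slot values Ordered list of typed values (possibly empty).
#' @slot dtype Canonical data-type token, or absent.
#' @slot unit Physical unit shared by all values, or absent.
#' @slot uncertainty Non-negative measurement uncertainty, or absent.
#' @slot valueOrigin Provenance of the values (e.g. a source file), or absent.
#' @slot reference External reference, or absent.
#' @slot id UUID identifying the property across files.
#'
#' @exportClass odmlProperty
setClass("odmlProperty", representation(
  name = "character",
  definition = "character",
  values = "list",
  dtype = "character",
  unit = "character",
  uncertainty = "numeric",
  valueOrigin = "character",
  reference = "character",
  id = "character"
))

#' odML section: a named, typed grouping node
#'
#' Sections give the odML tree its semantic structure: a section groups
#' related properties (e.g. all settings of one amplifier) and may nest
#' subsections. Sections are addressed by a \code{"/"}-joined name path from
#' the document root, which is why section names may not contain \code{"/"}.
#'
#' @slot name Section name (non-empty, no \code{"/"}).
#' @slot type Section type token (e.g. \code{"subject"}), or absent.
#' @slot definition Optional free-text definition.
#' @slot reference External reference, or absent.
#' @slot link Path to a linked section in the same document, or absent
#'   (stored verbatim, never dereferenced).
#' @slot include Path/URL to an included section in another document, or
#'   absent (stored verbatim).
#' @slot repository Terminology repository URI, or absent.
#' @slot id UUID.
#' @slot sections Ordered list of subsections (\code{odmlSection}).
#' @slot properties Ordered list of \code{odmlProperty} objects.
#'
#' @exportClass odmlSection
setClass("odmlSection", representation(
  name = "character",
  type = "character",
  definition = "character",
  reference = "character",
  link = "character",
  include = "character",
  repository = "character",
  id = "character",
  sections = "list",
  properties = "list"
))

#' odML document: the root of a metadata tree
#'
#' The document holds file-level attributes (author, date, version,
#' repository) and the top-level sections. It carries no properties itself.
#'
#' @slot author Document author, or absent.
#' @slot date Document date as ISO \code{YYYY-MM-DD} text, or absent.
#' @slot version Free-text version, or absent.
#' @slot repository Terminology repository URI, or absent.
#' @slot sections Ordered list of top-level \code{odmlSection} objects.
#'
#' @exportClass odmlDocument
setClass("odmlDocument", representation(
  author = "character",
  date = "character",
  version = "character",
  repository = "character",
  sections = "list"
))

#' Data-type registry: canonical odML types, synonyms and defaults
#'
#' Manages the canonical odML data types, their synonyms (e.g.
#' \code{"integer"} for \code{int}), the per-type default values used when a
#' table cell is empty, and the string-to-typed coercions shared by all
#' readers and writers.
#'
#' @slot synonyms Named character vector mapping synonym token to canonical.
#' @slot defaults Named list mapping canonical type to its default value.
#'
#' @exportClass DtypeRegistry
setClass("DtypeRegistry", representation(
  synonyms = "character",
  defaults = "list"
))

#' Table layout: column selection, headers and compaction for the dialect
#'
#' Describes how a flat odML table is rendered: which canonical columns
#' appear, in which order, under which display headers, whether repeated
#' cells are compacted, and (for xlsx) the cell styling.
#'
#' @slot columns Ordered canonical column keys; must include
#'   \code{path_to_section}, \code{property_name} and \code{value}.
#' @slot headerMap Named character vector, canonical key to display header;
#'   injective over the selected columns.
#' @slot compaction Logical; blank cells identical to the cell above.
#' @slot style A \code{StyleSpec} or \code{NULL} (list of length 0/1
#'   internally).
#'
#' @exportClass TableLayout
setClass("TableLayout", representation(
  columns = "character",
  headerMap = "character",
  compaction = "logical",
  style = "list"
))

#' Style specification for xlsx output
#'
#' Fill colors (RGB hex, \code{"RRGGBB"}) used when writing xlsx tables:
#' alternating fills for section and property blocks, a highlight for value
#' cells that equal the registry default of their data type, and a highlight
#' (red by default) for missing values. Styling is presentation only and is
#' ignored when reading tables back.
#'
#' @slot sectionRowColors Two alternating fills keyed to section changes.
#' @slot propertyRowColors Two alternating fills keyed to property changes.
#' @slot defaultValueFill Fill for cells holding a registry default value.
#' @slot missingValueFill Fill for empty value cells (default red).
#' @slot headerFill Fill for the header row.
#'
#' @exportClass StyleSpec
setClass("StyleSpec", representation(
  sectionRowColors = "character",
  propertyRowColors = "character",
  defaultValueFill = "character",
  missingValueFill = "character",
  headerFill = "character"
))

#' Comparison table across sections of one document
#'
#' Presentation-only grid: one row per requested property, one column per
#' matched section (under the default orientation), each cell holding the
#' rendered value list with the unit appended. Not convertible back to odML.
#'
#' @slot rowLabels Row labels.
#' @slot colLabels Column labels.
#' @slot cells Character matrix of rendered text,
#'   \code{length(rowLabels) x length(colLabels)}.
#'
#' @exportClass CompareTable
setClass("CompareTable", representation(
  rowLabels = "character",
  colLabels = "character",
  cells = "matrix"
))

.checkName <- function(name, what) {
  if (length(name) != 1 || is.na(name) || !nzchar(name)) {
    return(sprintf("%s name must be a non-empty string", what))
  }
  if (grepl("/", name, fixed = TRUE)) {
    return(sprintf(
      "%s name '%s' contains the path delimiter '/'", what, name
    ))
  }
  NULL
}

setValidity("odmlProperty", function(object) {
  msgs <- character(0)
  msgs <- c(msgs, .checkName(object@name, "property"))
  if (length(object@id) != 1 || !isUuid(object@id)) {
    msgs <- c(msgs, "property id must be a valid UUID")
  }
  for (s in c("definition", "dtype", "unit", "valueOrigin", "reference")) {
    if (length(slot(object, s)) > 1) {
      msgs <- c(msgs, sprintf("property %s must be a single value or absent", s))
    }
  }
  if (length(object@uncertainty) > 1) {
    msgs <- c(msgs, "property uncertainty must be a single value or absent")
  }
  if (length(msgs)) msgs else TRUE
})

setValidity("odmlSection", function(object) {
  msgs <- character(0)
  msgs <- c(msgs, .checkName(object@name, "section"))
  if (length(object@id) != 1 || !isUuid(object@id)) {
    msgs <- c(msgs, "section id must be a valid UUID")
  }
  if (!all(vapply(object@sections, is, logical(1), "odmlSection"))) {
    msgs <- c(msgs, "subsections must be odmlSection objects")
  }
  if (!all(vapply(object@properties, is, logical(1), "odmlProperty"))) {
    msgs <- c(msgs, "properties must be odmlProperty objects")
  }
  if (length(msgs)) msgs else TRUE
})

setValidity("odmlDocument", function(object) {
  if (!all(vapply(object@sections, is, logical(1), "odmlSection"))) {
    return("document sections must be odmlSection objects")
  }
  TRUE
})

setValidity("TableLayout", function(object) {
  msgs <- character(0)
  mandatory <- c("path_to_section", "property_name", "value")
  missing <- setdiff(mandatory, object@columns)
  if (length(missing)) {
    msgs <- c(msgs, sprintf(
      "layout is missing mandatory column(s): %s", paste(missing, collapse = ", ")
    ))
  }
  unknown <- setdiff(object@columns, names(object@headerMap))
  if (length(unknown)) {
    msgs <- c(msgs, sprintf(
      "no display header for column(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  heads <- object@headerMap[intersect(object@columns, names(object@headerMap))]
  if (anyDuplicated(heads)) {
    msgs <- c(msgs, "header map is not injective over the selected columns")
  }
  if (length(msgs)) msgs else TRUE
})

.isHex <- function(x) grepl("^[0-9A-Fa-f]{6}$", x)

setValidity("StyleSpec", function(object) {
  cols <- c(
    object@sectionRowColors, object@propertyRowColors,
    object@defaultValueFill, object@missingValueFill, object@headerFill
  )
  if (!all(.isHex(cols))) return("fill colors must be RRGGBB hex strings")
  if (length(object@sectionRowColors) != 2 || length(object@propertyRowColors) != 2) {
    return("section/property row colors must each provide two alternating fills")
  }
  TRUE
})

setValidity("CompareTable", function(object) {
  ok <- is.character(object@cells) &&
    nrow(object@cells) == length(object@rowLabels) &&
    ncol(object@cells) == length(object@colLabels)
  if (ok) TRUE else "cell matrix shape must match row/column labels"
})
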