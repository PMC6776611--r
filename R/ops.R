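# Collection-level operations: template generation, merging with optional
# value overwriting, multi-step property filtering, comparison tables.

## ---- template ----

#' Write a template table
#'
#' Writes a table (csv or xlsx by extension) that fixes the shape of future
#' records: the document-attribute row, the layout's headers, and either
#' the rows of a skeleton document or a single generic placeholder row.
#' Values the skeleton designer pre-filled (e.g. a default experimenter
#' name, a fixed unit) are kept; everything else stays empty for the person
#' filling the sheet out.
#'
#' @param path Output file (\code{.csv} or \code{.xlsx}).
#' @param layout A \linkS4class{TableLayout}.
#' @param skeleton An \linkS4class{odmlDocument} whose structure the
#'   template should follow, or \code{NULL} for a generic one-row template.
#' @param registry Data-type registry.
#' @return Invisibly, \code{path}.
#' @export
createTemplate <- function(path, layout = tableLayout(), skeleton = NULL,
                           registry = dtypeRegistry()) {
  if (is.null(skeleton)) {
    skeleton <- odmlDocument(sections = list(
      odmlSection("Section", type = "undefined", properties = list(
        odmlProperty("Property", dtype = "string")
      ))
    ))
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = writeOdmlCsv(skeleton, path, layout, registry),
    xlsx = writeOdmlXlsx(skeleton, path, layout, registry),
    odmlStop("odmlUsageError",
             "template extension must be .csv or .xlsx, got '%s'", ext)
  )
  invisible(path)
}

## ---- merge ----

.mergeScalar <- function(targetVal, sourceVal, overwrite) {
  if (length(targetVal) == 0) return(sourceVal)
  if (length(sourceVal) == 0) return(targetVal)
  if (overwrite) sourceVal else targetVal
}

.mergeProperty <- function(target, source, overwrite, path) {
  if (!overwrite) {
    # appending values requires agreeing value-level attributes
    for (f in c("dtype", "unit")) {
      tv <- slot(target, f); sv <- slot(source, f)
      if (length(tv) && length(sv) && !identical(tv, sv)) {
        odmlStop("odmlMergeError",
                 "conflicting %s ('%s' vs '%s') for property '%s:%s'",
                 f, tv, sv, path, target@name)
      }
    }
    tu <- target@uncertainty; su <- source@uncertainty
    if (length(tu) && length(su) && tu != su) {
      odmlStop("odmlMergeError",
               "conflicting uncertainty for property '%s:%s'",
               path, target@name)
    }
  }
  values <- if (overwrite) {
    if (length(source@values)) source@values else target@values
  } else {
    c(target@values, source@values)
  }
  new("odmlProperty",
    name = target@name,
    definition = .mergeScalar(target@definition, source@definition, overwrite),
    values = values,
    dtype = .mergeScalar(target@dtype, source@dtype, overwrite),
    unit = .mergeScalar(target@unit, source@unit, overwrite),
    uncertainty = .mergeScalar(target@uncertainty, source@uncertainty, overwrite),
    valueOrigin = .mergeScalar(target@valueOrigin, source@valueOrigin, overwrite),
    reference = .mergeScalar(target@reference, source@reference, overwrite),
    id = target@id
  )
}

.mergeSection <- function(target, source, overwrite, path) {
  spath <- paste0(path, "/", target@name)
  props <- target@properties
  pnames <- vapply(props, function(p) p@name, "")
  for (sp in source@properties) {
    idx <- match(sp@name, pnames)
    if (is.na(idx)) {
      props <- c(props, sp)
      pnames <- c(pnames, sp@name)
    } else {
      props[[idx]] <- .mergeProperty(props[[idx]], sp, overwrite, spath)
    }
  }
  secs <- target@sections
  snames <- vapply(secs, function(s) s@name, "")
  for (ss in source@sections) {
    idx <- match(ss@name, snames)
    if (is.na(idx)) {
      secs <- c(secs, ss)
      snames <- c(snames, ss@name)
    } else {
      secs[[idx]] <- .mergeSection(secs[[idx]], ss, overwrite, spath)
    }
  }
  new("odmlSection",
    name = target@name,
    type = .mergeScalar(target@type, source@type, overwrite),
    definition = .mergeScalar(target@definition, source@definition, overwrite),
    reference = .mergeScalar(target@reference, source@reference, overwrite),
    link = .mergeScalar(target@link, source@link, overwrite),
    include = .mergeScalar(target@include, source@include, overwrite),
    repository = .mergeScalar(target@repository, source@repository, overwrite),
    id = target@id,
    sections = secs,
    properties = props
  )
}

#' Merge two documents
#'
#' Sections and properties of the source are added to the target: entities
#' present in both are merged recursively by name, entities only in the
#' source are appended (keeping their UUIDs), and the target's UUIDs are
#' preserved for everything that already existed. For a property present in
#' both documents, the source values are appended to the target's value
#' list by default; with \code{overwriteValues = TRUE} non-empty source
#' value lists replace the target's. Appending requires the two properties
#' to agree on dtype, unit and uncertainty (a conflict is an error).
#' Scalar-attribute conflicts resolve to the target (append mode) or the
#' source (overwrite mode).
#'
#' @param target,source \linkS4class{odmlDocument} objects; both must
#'   validate.
#' @param overwriteValues Replace instead of append coinciding properties'
#'   values.
#' @param registry Data-type registry.
#' @return The merged, validated \linkS4class{odmlDocument}.
#' @export
mergeDocuments <- function(target, source, overwriteValues = FALSE,
                           registry = dtypeRegistry()) {
  .stopIfInvalid(target, registry)
  .stopIfInvalid(source, registry)
  secs <- target@sections
  snames <- vapply(secs, function(s) s@name, "")
  for (ss in source@sections) {
    idx <- match(ss@name, snames)
    if (is.na(idx)) {
      secs <- c(secs, ss)
      snames <- c(snames, ss@name)
    } else {
      secs[[idx]] <- .mergeSection(secs[[idx]], ss, overwriteValues, "")
    }
  }
  out <- new("odmlDocument",
    author = .mergeScalar(target@author, source@author, overwriteValues),
    date = .mergeScalar(target@date, source@date, overwriteValues),
    version = .mergeScalar(target@version, source@version, overwriteValues),
    repository = .mergeScalar(target@repository, source@repository,
                              overwriteValues),
    sections = secs
  )
  .stopIfInvalid(out, registry)
  out
}

## ---- filter ----

.FILTER_FIELDS <- c(
  "path", "section_name", "section_type", "property_name", "value",
  "data_unit", "odml_data_type", "value_count"
)
.FILTER_OPS <- c("equals", "contains", "matches", "is_empty")

#' Build one filter comparison
#'
#' @param field One of \code{path}, \code{section_name},
#'   \code{section_type}, \code{property_name}, \code{value},
#'   \code{data_unit}, \code{odml_data_type}, \code{value_count}.
#' @param op \code{equals}, \code{contains}, \code{matches} (regular
#'   expression) or \code{is_empty}.
#' @param operand Comparison operand (unused for \code{is_empty}). A
#'   comparison on \code{value} holds when any value of the property
#'   satisfies it; \code{value_count} compares numerically.
#' @return A comparison object for \code{\link{filterStep}}.
#' @export
comparison <- function(field, op, operand = NULL) {
  if (!field %in% .FILTER_FIELDS) {
    odmlStop("odmlFilterSpecError", "unknown filter field '%s'; known: %s",
             field, paste(.FILTER_FIELDS, collapse = ", "))
  }
  if (!op %in% .FILTER_OPS) {
    odmlStop("odmlFilterSpecError", "unknown filter operator '%s'; known: %s",
             op, paste(.FILTER_OPS, collapse = ", "))
  }
  if (is.null(operand) && op != "is_empty") {
    odmlStop("odmlFilterSpecError", "operator '%s' needs an operand", op)
  }
  structure(list(field = field, op = op, operand = operand),
            class = "odmlComparison")
}

#' Build one filtering step
#'
#' A step keeps or rejects properties according to its comparisons,
#' combined with \code{all} (conjunction) or \code{any} (disjunction), or
#' according to a custom predicate over the property record. Steps compose
#' left to right in a \code{\link{filterSpec}}: each step's output feeds
#' the next, so \code{keep} intersects and \code{reject} subtracts.
#'
#' @param mode \code{"keep"} or \code{"reject"}.
#' @param comparisons List of \code{\link{comparison}} objects.
#' @param combine \code{"all"} or \code{"any"}.
#' @param custom Optional predicate \code{function(record)} returning a
#'   logical; the record is a list with fields \code{path},
#'   \code{section_name}, \code{section_type}, \code{property_name},
#'   \code{values} (rendered text), \code{data_unit},
#'   \code{odml_data_type}, \code{value_count}.
#' @return A filter-step object.
#' @export
filterStep <- function(mode = c("keep", "reject"), comparisons = list(),
                       combine = c("all", "any"), custom = NULL) {
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  if (!length(comparisons) && is.null(custom)) {
    odmlStop("odmlFilterSpecError",
             "a filter step needs at least one comparison or a custom predicate")
  }
  ok <- vapply(comparisons, inherits, logical(1), "odmlComparison")
  if (!all(ok)) {
    odmlStop("odmlFilterSpecError",
             "comparisons must be built with comparison()")
  }
  structure(
    list(mode = mode, comparisons = comparisons, combine = combine,
         custom = custom),
    class = "odmlFilterStep"
  )
}

#' Build a multi-step filter specification
#'
#' @param ... \code{\link{filterStep}} objects, applied left to right.
#' @return A filter-spec object for \code{\link{filterDocument}}.
#' @examples
#' # the flagship filter: properties with no values
#' emptyValueSpec <- filterSpec(
#'   filterStep("keep", list(comparison("value_count", "equals", 0)))
#' )
#' @export
filterSpec <- function(...) {
  steps <- list(...)
  if (length(steps) == 1 && is.list(steps[[1]]) &&
      !inherits(steps[[1]], "odmlFilterStep")) {
    steps <- steps[[1]]
  }
  if (!length(steps)) {
    odmlStop("odmlFilterSpecError", "a filter spec needs at least one step")
  }
  ok <- vapply(steps, inherits, logical(1), "odmlFilterStep")
  if (!all(ok)) {
    odmlStop("odmlFilterSpecError", "steps must be built with filterStep()")
  }
  structure(list(steps = steps), class = "odmlFilterSpec")
}

# One record per property, used by predicates and by the compare oracle.
.propertyRecords <- function(document, registry = dtypeRegistry()) {
  out <- list()
  walk <- function(sec, parent) {
    path <- paste0(parent, "/", sec@name)
    for (p in sec@properties) {
      out[[length(out) + 1L]] <<- list(
        path = path,
        section_name = sec@name,
        section_type = orNA(sec@type),
        property_name = p@name,
        values = vapply(p@values, function(v) {
          formatValue(v, if (length(p@dtype)) p@dtype else NULL, registry)
        }, ""),
        data_unit = orNA(p@unit),
        odml_data_type = orNA(p@dtype),
        value_count = length(p@values)
      )
    }
    for (sub in sec@sections) walk(sub, path)
  }
  for (s in document@sections) walk(s, "")
  out
}

.evalComparison <- function(cmp, rec) {
  fieldVal <- rec[[cmp$field]]
  if (cmp$op == "is_empty") {
    return(if (cmp$field == "value") rec$value_count == 0
           else if (cmp$field == "value_count") rec$value_count == 0
           else is.na(fieldVal) || !nzchar(fieldVal))
  }
  if (cmp$field == "value_count") {
    return(switch(cmp$op,
      equals = rec$value_count == as.numeric(cmp$operand),
      contains = grepl(as.character(cmp$operand),
                       as.character(rec$value_count), fixed = TRUE),
      matches = grepl(as.character(cmp$operand),
                      as.character(rec$value_count))
    ))
  }
  if (cmp$field == "value") {
    vals <- rec$values
    if (!length(vals)) return(FALSE)
    return(switch(cmp$op,
      equals = any(vals == as.character(cmp$operand)),
      contains = any(grepl(as.character(cmp$operand), vals, fixed = TRUE)),
      matches = any(grepl(as.character(cmp$operand), vals))
    ))
  }
  if (is.na(fieldVal)) return(FALSE)
  switch(cmp$op,
    equals = fieldVal == as.character(cmp$operand),
    contains = grepl(as.character(cmp$operand), fieldVal, fixed = TRUE),
    matches = grepl(as.character(cmp$operand), fieldVal)
  )
}

.evalStep <- function(step, rec) {
  hits <- vapply(step$comparisons, .evalComparison, logical(1), rec = rec)
  if (!is.null(step$custom)) {
    hits <- c(hits, isTRUE(step$custom(rec)))
  }
  matched <- if (identical(step$combine, "all")) all(hits) else any(hits)
  if (identical(step$mode, "keep")) matched else !matched
}

# TRUE for the properties that survive all steps.
.filterSurvivors <- function(records, spec) {
  keep <- rep(TRUE, length(records))
  for (step in spec$steps) {
    for (i in seq_along(records)) {
      if (keep[i]) keep[i] <- .evalStep(step, records[[i]])
    }
  }
  keep
}

#' Filter a document to a subset of its properties
#'
#' Applies the steps of the spec left to right at property granularity and
#' returns a document containing exactly the surviving properties plus the
#' ancestor sections needed to house them (attributes copied verbatim,
#' UUIDs preserved). The input is not modified. The flagship use is
#' extracting all properties with no values to surface missing entries:
#' \code{filterSpec(filterStep("keep", list(comparison("value_count",
#' "equals", 0))))}.
#'
#' @param document An \linkS4class{odmlDocument}.
#' @param spec An \code{\link{filterSpec}} object.
#' @param registry Data-type registry.
#' @return The filtered \linkS4class{odmlDocument}.
#' @export
filterDocument <- function(document, spec, registry = dtypeRegistry()) {
  if (!inherits(spec, "odmlFilterSpec")) {
    odmlStop("odmlFilterSpecError", "spec must be built with filterSpec()")
  }
  .stopIfInvalid(document, registry)
  records <- .propertyRecords(document, registry)
  keep <- .filterSurvivors(records, spec)
  keptKeys <- vapply(
    records[keep],
    function(r) paste(r$path, r$property_name, sep = "\r"), ""
  )
  prune <- function(sec, parent) {
    path <- paste0(parent, "/", sec@name)
    props <- Filter(
      function(p) paste(path, p@name, sep = "\r") %in% keptKeys,
      sec@properties
    )
    subs <- list()
    for (sub in sec@sections) {
      pr <- prune(sub, path)
      if (!is.null(pr)) subs <- c(subs, pr)
    }
    if (!length(props) && !length(subs)) return(NULL)
    out <- sec
    out@properties <- props
    out@sections <- subs
    out
  }
  secs <- list()
  for (s in document@sections) {
    pr <- prune(s, "")
    if (!is.null(pr)) secs <- c(secs, pr)
  }
  out <- document
  out@sections <- secs
  out
}

## ---- compare ----

#' Build a comparison table across sections
#'
#' Creates a presentation-only overview: one column per section matched by
#' the glob selector (in document order), one row per requested property.
#' Each cell renders the property's value list in that section, the unit
#' appended directly to each value with no space (weight \code{5.0} with
#' unit \code{g} renders \code{"5.0g"}), multiple values joined by
#' \code{", "}. A property missing from a section leaves an empty cell.
#' The table cannot be converted back to odML.
#'
#' @param document An \linkS4class{odmlDocument}.
#' @param propertyNames Ordered, duplicate-free property names (rows).
#' @param sectionSelector Glob pattern on section names, e.g.
#'   \code{"Scores_*"}; sections anywhere in the tree are matched.
#' @param orientation \code{"sections-as-columns"} (default) or
#'   \code{"sections-as-rows"}.
#' @param registry Data-type registry.
#' @return A \linkS4class{CompareTable}.
#' @examples
#' doc <- buildSubjectDocument("enriched")
#' compareSections(doc, c("Date", "Weight"), "Scores_*")
#' @export
compareSections <- function(document, propertyNames, sectionSelector = "*",
                            orientation = c("sections-as-columns",
                                            "sections-as-rows"),
                            registry = dtypeRegistry()) {
  orientation <- match.arg(orientation)
  if (!length(propertyNames)) {
    odmlStop("odmlCompareSpecError", "propertyNames must be non-empty")
  }
  if (anyDuplicated(propertyNames)) {
    odmlStop("odmlCompareSpecError", "duplicate property names in spec")
  }
  .stopIfInvalid(document, registry)
  rx <- utils::glob2rx(sectionSelector)
  matched <- Filter(
    function(e) grepl(rx, e$section@name),
    .walkSections(document)
  )
  cells <- matrix(
    "", nrow = length(propertyNames), ncol = length(matched)
  )
  colLabels <- vapply(matched, function(e) e$section@name, "")
  for (j in seq_along(matched)) {
    sec <- matched[[j]]$section
    pn <- vapply(sec@properties, function(p) p@name, "")
    for (i in seq_along(propertyNames)) {
      idx <- match(propertyNames[i], pn)
      if (is.na(idx)) next
      p <- sec@properties[[idx]]
      vals <- vapply(p@values, function(v) {
        formatValue(v, if (length(p@dtype)) p@dtype else NULL, registry)
      }, "")
      if (length(p@unit)) vals <- paste0(vals, p@unit)
      cells[i, j] <- paste(vals, collapse = ", ")
    }
  }
  if (identical(orientation, "sections-as-rows")) {
    new("CompareTable",
      rowLabels = colLabels, colLabels = as.character(propertyNames),
      cells = t(cells)
    )
  } else {
    new("CompareTable",
      rowLabels = as.character(propertyNames), colLabels = colLabels,
      cells = cells
    )
  }
}

setMethod("show", "CompareTable", function(object) {
  m <- rbind(
    c("", object@colLabels),
    cbind(object@rowLabels, object@cells)
  )
  widths <- apply(nchar(m), 2, max)
  for (i in seq_len(nrow(m))) {
    padded <- vapply(seq_len(ncol(m)), function(j) {
      formatC(m[i, j], width = widths[j], flag = "-")
    }, "")
    cat(paste(padded, collapse = "  "), "\n")
  }
})

#' Write a comparison table to csv or xlsx
#'
#' The grid equals the table: a label row, a label column, and the
#' rendered cells. xlsx output fills the header row/column when a style is
#' given; csv carries no formatting.
#'
#' @param table A \linkS4class{CompareTable}.
#' @param path Output file (\code{.csv} or \code{.xlsx}).
#' @param style A \linkS4class{StyleSpec} or \code{NULL} (xlsx only).
#' @return Invisibly, \code{path}.
#' @export
writeCompareTable <- function(table, path, style = NULL) {
  grid <- rbind(
    c("", table@colLabels),
    cbind(table@rowLabels, table@cells)
  )
  ext <- tolower(tools::file_ext(path))
  if (identical(ext, "csv")) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    utils::write.table(
      grid, con, sep = ",", quote = TRUE, row.names = FALSE,
      col.names = FALSE, eol = "\n", fileEncoding = "UTF-8",
      qmethod = "double"
    )
  } else if (identical(ext, "xlsx")) {
    fills <- NULL
    if (!is.null(style)) {
      fills <- matrix(NA_character_, nrow = nrow(grid), ncol = ncol(grid))
      fills[1, ] <- style@headerFill
      fills[, 1] <- style@headerFill
    }
    .xlsxWriteGrid(grid, path, fills)
  } else {
    odmlStop("odmlUsageError",
             "comparison table extension must be .csv or .xlsx, got '%s'", ext)
  }
  invisible(path)
}

#' Read a comparison-table grid back (for checking, not for odML)
#'
#' @param path csv or xlsx file written by \code{\link{writeCompareTable}}.
#' @return Character matrix of the grid.
#' @export
readCompareGrid <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (identical(ext, "csv")) {
    g <- as.matrix(utils::read.csv(
      path, header = FALSE, colClasses = "character",
      fileEncoding = "UTF-8", stringsAsFactors = FALSE,
      blank.lines.skip = FALSE
    ))
    dimnames(g) <- NULL
    g
  } else if (identical(ext, "xlsx")) {
    .xlsxReadGrid(path)
  } else {
    odmlStop("odmlUsageError", "unknown extension '%s'", ext)
  }
}
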