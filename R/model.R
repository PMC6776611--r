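# Constructors, accessors, validation and equality for the odML 1.4 model.

#' Construct an odML property
#'
#' @param name Property name (non-empty, no \code{"/"}).
#' @param values Typed values: a list or an atomic vector (converted to a
#'   list). Empty by default.
#' @param dtype Canonical data-type token or synonym, or \code{NULL}.
#' @param unit,uncertainty,definition,valueOrigin,reference Optional
#'   value-level and descriptive attributes shared by all values.
#' @param id UUID string; a fresh version-4 UUID is minted when \code{NULL}.
#' @param registry Registry used to resolve \code{dtype} synonyms.
#' @return An \linkS4class{odmlProperty}.
#' @examples
#' odmlProperty("Weight", values = c(5.0, 5.5), dtype = "float", unit = "g")
#' @export
odmlProperty <- function(name, values = list(), dtype = NULL, unit = NULL,
                         uncertainty = NULL, definition = NULL,
                         valueOrigin = NULL, reference = NULL, id = NULL,
                         registry = dtypeRegistry()) {
  if (!is.list(values)) values <- as.list(values)
  dt <- asScalarChr(dtype)
  if (length(dt)) dt <- resolveDtype(dt, registry)
  new("odmlProperty",
    name = as.character(name),
    definition = asScalarChr(definition),
    values = values,
    dtype = dt,
    unit = asScalarChr(unit),
    uncertainty = asScalarNum(uncertainty),
    valueOrigin = asScalarChr(valueOrigin),
    reference = asScalarChr(reference),
    id = if (is.null(id)) mintUuid() else as.character(id)
  )
}

#' Construct an odML section
#'
#' @param name Section name (non-empty, no \code{"/"}).
#' @param type Section type token, or \code{NULL}.
#' @param definition,reference,link,include,repository Optional attributes;
#'   \code{link}/\code{include} are stored verbatim and never dereferenced.
#' @param sections List of subsections.
#' @param properties List of \linkS4class{odmlProperty} objects.
#' @param id UUID string; minted when \code{NULL}.
#' @return An \linkS4class{odmlSection}.
#' @export
odmlSection <- function(name, type = NULL, definition = NULL,
                        reference = NULL, link = NULL, include = NULL,
                        repository = NULL, sections = list(),
                        properties = list(), id = NULL) {
  new("odmlSection",
    name = as.character(name),
    type = asScalarChr(type),
    definition = asScalarChr(definition),
    reference = asScalarChr(reference),
    link = asScalarChr(link),
    include = asScalarChr(include),
    repository = asScalarChr(repository),
    id = if (is.null(id)) mintUuid() else as.character(id),
    sections = sections,
    properties = properties
  )
}

#' Construct an odML document
#'
#' @param author,date,version,repository Optional document attributes;
#'   \code{date} is ISO \code{YYYY-MM-DD} text.
#' @param sections List of top-level \linkS4class{odmlSection} objects.
#' @return An \linkS4class{odmlDocument}.
#' @examples
#' doc <- odmlDocument(author = "Alice", sections = list(odmlSection("Subject")))
#' @export
odmlDocument <- function(author = NULL, date = NULL, version = NULL,
                         repository = NULL, sections = list()) {
  new("odmlDocument",
    author = asScalarChr(author),
    date = asScalarChr(date),
    version = asScalarChr(version),
    repository = asScalarChr(repository),
    sections = sections
  )
}

#' @rdname sections
#' @export
setGeneric("sections", function(x) standardGeneric("sections"))

#' Access subsections of a document or section
#'
#' @param x An \linkS4class{odmlDocument} or \linkS4class{odmlSection}.
#' @return List of \linkS4class{odmlSection} objects.
#' @export
setMethod("sections", "odmlDocument", function(x) x@sections)

#' @rdname sections
setMethod("sections", "odmlSection", function(x) x@sections)

#' @rdname properties
#' @export
setGeneric("properties", function(x) standardGeneric("properties"))

#' Access properties of a section
#'
#' @param x An \linkS4class{odmlSection}.
#' @return List of \linkS4class{odmlProperty} objects.
#' @export
setMethod("properties", "odmlSection", function(x) x@properties)

#' @rdname odmlName
#' @export
setGeneric("odmlName", function(x) standardGeneric("odmlName"))

#' Name of an odML entity
#'
#' @param x An \linkS4class{odmlSection} or \linkS4class{odmlProperty}.
#' @return The entity name.
#' @export
setMethod("odmlName", "odmlSection", function(x) x@name)

#' @rdname odmlName
setMethod("odmlName", "odmlProperty", function(x) x@name)

#' @rdname propValues
#' @export
setGeneric("propValues", function(x) standardGeneric("propValues"))

#' Values of a property
#'
#' @param x An \linkS4class{odmlProperty}.
#' @return The ordered list of typed values.
#' @export
setMethod("propValues", "odmlProperty", function(x) x@values)

setMethod("show", "odmlProperty", function(object) {
  vals <- vapply(object@values, function(v) formatValue(v, object@dtype), "")
  cat(sprintf(
    "odmlProperty '%s'%s: [%s]%s\n",
    object@name,
    if (length(object@dtype)) paste0(" <", object@dtype, ">") else "",
    paste(vals, collapse = ", "),
    if (length(object@unit)) paste0(" ", object@unit) else ""
  ))
})

.showSection <- function(s, indent) {
  cat(sprintf(
    "%s+ %s%s (%d properties)\n",
    strrep("  ", indent), s@name,
    if (length(s@type)) paste0(" [", s@type, "]") else "",
    length(s@properties)
  ))
  for (sub in s@sections) .showSection(sub, indent + 1)
}

setMethod("show", "odmlSection", function(object) .showSection(object, 0))

setMethod("show", "odmlDocument", function(object) {
  cnt <- documentCounts(object)
  cat(sprintf(
    "odmlDocument%s: %d sections, %d properties, %d values\n",
    if (length(object@author)) paste0(" by ", object@author) else "",
    cnt["sections"], cnt["properties"], cnt["values"]
  ))
  for (s in object@sections) .showSection(s, 1)
})

#' Count entities in a document
#'
#' @param document An \linkS4class{odmlDocument}.
#' @return Named integer vector with elements \code{sections},
#'   \code{properties} and \code{values}.
#' @export
documentCounts <- function(document) {
  ns <- 0L; np <- 0L; nv <- 0L
  walk <- function(sec) {
    ns <<- ns + 1L
    np <<- np + length(sec@properties)
    nv <<- nv + sum(vapply(sec@properties, function(p) length(p@values), 0L))
    for (sub in sec@sections) walk(sub)
  }
  for (s in document@sections) walk(s)
  c(sections = ns, properties = np, values = nv)
}

# Depth-first (pre-order) walk yielding (path, section) pairs.
.walkSections <- function(document) {
  out <- list()
  walk <- function(sec, parent) {
    path <- paste0(parent, "/", sec@name)
    out[[length(out) + 1L]] <<- list(path = path, section = sec)
    for (sub in sec@sections) walk(sub, path)
  }
  for (s in document@sections) walk(s, "")
  out
}

#' Validate an odML document
#'
#' Checks every model invariant and reports all violations instead of
#' raising: unique sibling section names, unique property names within a
#' section, valid UUIDs, non-negative uncertainties, and conformity of each
#' value to its property's data type. The document is not modified; an empty
#' report means the document is valid.
#'
#' @param document An \linkS4class{odmlDocument}.
#' @param registry Registry used for dtype conformity checks.
#' @return A data frame with columns \code{path}, \code{rule},
#'   \code{message}; zero rows when the document satisfies all invariants.
#' @examples
#' nrow(validateDocument(odmlDocument()))  # 0
#' @export
validateDocument <- function(document, registry = dtypeRegistry()) {
  viol <- list()
  add <- function(path, rule, message) {
    viol[[length(viol) + 1L]] <<- data.frame(
      path = path, rule = rule, message = message, stringsAsFactors = FALSE
    )
  }
  checkSiblings <- function(secs, parentPath) {
    nms <- vapply(secs, function(s) s@name, "")
    dup <- unique(nms[duplicated(nms)])
    for (d in dup) {
      add(parentPath, "duplicate_sibling_section",
          sprintf("duplicate sibling section name '%s'", d))
    }
  }
  checkSiblings(document@sections, "/")
  walk <- function(sec, parent) {
    path <- paste0(parent, "/", sec@name)
    if (!isUuid(sec@id)) {
      add(path, "invalid_uuid", "section id is not a valid UUID")
    }
    checkSiblings(sec@sections, path)
    pnms <- vapply(sec@properties, function(p) p@name, "")
    for (d in unique(pnms[duplicated(pnms)])) {
      add(path, "duplicate_property",
          sprintf("duplicate property name '%s'", d))
    }
    for (p in sec@properties) {
      ppath <- paste0(path, ":", p@name)
      if (!isUuid(p@id)) {
        add(ppath, "invalid_uuid", "property id is not a valid UUID")
      }
      if (length(p@uncertainty) && (is.na(p@uncertainty) || p@uncertainty < 0)) {
        add(ppath, "negative_uncertainty",
            "uncertainty must be a non-negative number")
      }
      if (length(p@dtype)) {
        ok <- tryCatch(
          vapply(p@values, conformsTo, logical(1),
                 dtype = p@dtype, registry = registry),
          odmlDtypeError = function(e) {
            add(ppath, "unknown_dtype", conditionMessage(e))
            logical(0)
          }
        )
        if (length(ok) && !all(ok)) {
          add(ppath, "dtype_mismatch", sprintf(
            "value(s) %s do not conform to dtype '%s'",
            paste(which(!ok), collapse = ", "), p@dtype
          ))
        }
      }
    }
    for (sub in sec@sections) walk(sub, path)
  }
  for (s in document@sections) walk(s, "")
  if (length(viol)) do.call(rbind, viol) else {
    data.frame(path = character(0), rule = character(0),
               message = character(0), stringsAsFactors = FALSE)
  }
}

.stopIfInvalid <- function(document, registry = dtypeRegistry()) {
  rep <- validateDocument(document, registry)
  if (nrow(rep)) {
    odmlStop("odmlValidationError", "document fails validation:\n%s",
             paste(sprintf("  [%s] %s: %s", rep$rule, rep$path, rep$message),
                   collapse = "\n"))
  }
  invisible(document)
}

.valuesEqual <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (length(a) == 0) return(TRUE)
  all(mapply(function(x, y) {
    attributes(x)$odml_default <- NULL
    attributes(y)$odml_default <- NULL
    isTRUE(all.equal(x, y, check.attributes = FALSE))
  }, a, b))
}

.scalarEqual <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  length(a) == 0 || isTRUE(all.equal(a, b))
}

.propsEqual <- function(a, b, ignoreIds, lossy) {
  fields <- c("name", "definition", "dtype", "unit", "uncertainty")
  if (!lossy) fields <- c(fields, "valueOrigin", "reference")
  else fields <- c(fields, "valueOrigin", "reference")
  for (f in fields) {
    if (!.scalarEqual(slot(a, f), slot(b, f))) return(FALSE)
  }
  if (!ignoreIds && !identical(a@id, b@id)) return(FALSE)
  .valuesEqual(a@values, b@values)
}

.sectionsEqual <- function(a, b, ignoreIds, lossy) {
  # The tabular dialect carries only name/type/definition at section level,
  # and only for sections that own at least one property (rows exist for
  # them); a property-less section survives just as a path component.
  fields <- if (lossy) {
    if (length(a@properties) == 0 && length(b@properties) == 0) "name"
    else c("name", "type", "definition")
  } else {
    c("name", "type", "definition", "reference", "link", "include",
      "repository")
  }
  for (f in fields) {
    if (!.scalarEqual(slot(a, f), slot(b, f))) return(FALSE)
  }
  if (!ignoreIds && !identical(a@id, b@id)) return(FALSE)
  if (length(a@properties) != length(b@properties)) return(FALSE)
  if (length(a@sections) != length(b@sections)) return(FALSE)
  for (i in seq_along(a@properties)) {
    if (!.propsEqual(a@properties[[i]], b@properties[[i]], ignoreIds, lossy)) {
      return(FALSE)
    }
  }
  for (i in seq_along(a@sections)) {
    if (!.sectionsEqual(a@sections[[i]], b@sections[[i]], ignoreIds, lossy)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Structural equality of odML documents
#'
#' Compares two documents attribute by attribute, in order. With
#' \code{ignoreIds = TRUE} entity UUIDs are not compared (the tabular
#' dialect does not carry them, so table round trips mint fresh ones). With
#' \code{ignoreLossy = TRUE} the section attributes the tabular dialect does
#' not represent (\code{link}, \code{include}, \code{repository}) are also
#' excluded.
#'
#' @param a,b \linkS4class{odmlDocument} objects.
#' @param ignoreIds Skip UUID comparison.
#' @param ignoreLossy Skip the tabular dialect's declared-lossy fields.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
odmlEquals <- function(a, b, ignoreIds = FALSE, ignoreLossy = FALSE) {
  for (f in c("author", "date", "version", "repository")) {
    if (!.scalarEqual(slot(a, f), slot(b, f))) return(FALSE)
  }
  if (length(a@sections) != length(b@sections)) return(FALSE)
  for (i in seq_along(a@sections)) {
    if (!.sectionsEqual(a@sections[[i]], b@sections[[i]], ignoreIds, ignoreLossy)) {
      return(FALSE)
    }
  }
  TRUE
}

#' Find a section by its path
#'
#' @param document An \linkS4class{odmlDocument}.
#' @param path \code{"/"}-joined section-name path from the root, e.g.
#'   \code{"/Subject/Scores_2000-01-01"}.
#' @return The \linkS4class{odmlSection}, or \code{NULL} when absent.
#' @export
findSection <- function(document, path) {
  parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
  secs <- document@sections
  cur <- NULL
  for (part in parts) {
    idx <- which(vapply(secs, function(s) s@name, "") == part)
    if (!length(idx)) return(NULL)
    cur <- secs[[idx[1]]]
    secs <- cur@sections
  }
  cur
}

#' Find a property by section path and name
#'
#' @param document An \linkS4class{odmlDocument}.
#' @param path Section path as for \code{\link{findSection}}.
#' @param name Property name.
#' @return The \linkS4class{odmlProperty}, or \code{NULL} when absent.
#' @export
findProperty <- function(document, path, name) {
  sec <- findSection(document, path)
  if (is.null(sec)) return(NULL)
  idx <- which(vapply(sec@properties, function(p) p@name, "") == name)
  if (!length(idx)) return(NULL)
  sec@properties[[idx[1]]]
}
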