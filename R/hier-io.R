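# Hierarchical serializations: odML XML (canonical, version 1.4), JSON and
# YAML mirrors, and the automatic upgrade of legacy v1.3 XML files.

.FORMATS <- c("xml", "json", "yaml")

.formatFromPath <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    odml = "xml", xml = "xml",
    json = "json",
    yaml = "yaml", yml = "yaml",
    NA_character_
  )
}

.sniffFormat <- function(path) {
  head <- paste(readLines(path, n = 5L, warn = FALSE), collapse = "\n")
  first <- sub("^\\s*", "", head)
  if (startsWith(first, "<")) "xml"
  else if (startsWith(first, "{")) "json"
  else "yaml"
}

.resolveFormat <- function(path, format) {
  if (identical(format, "auto")) {
    f <- .formatFromPath(path)
    if (is.na(f)) f <- .sniffFormat(path)
    f
  } else {
    if (!format %in% .FORMATS) {
      odmlStop("odmlFormatError", "unknown serialization format '%s'", format)
    }
    format
  }
}

## ---- XML ----

.xmlAddText <- function(parent, tag, value) {
  if (length(value)) {
    xml2::xml_add_child(parent, tag, as.character(value))
  }
  invisible(parent)
}

.propertyToXml <- function(parent, prop) {
  node <- xml2::xml_add_child(parent, "property")
  .xmlAddText(node, "name", prop@name)
  .xmlAddText(node, "definition", prop@definition)
  .xmlAddText(node, "type", prop@dtype)
  .xmlAddText(node, "unit", prop@unit)
  if (length(prop@uncertainty)) {
    .xmlAddText(node, "uncertainty", formatValue(prop@uncertainty, "float"))
  }
  .xmlAddText(node, "value_origin", prop@valueOrigin)
  .xmlAddText(node, "reference", prop@reference)
  .xmlAddText(node, "id", prop@id)
  for (v in prop@values) {
    xml2::xml_add_child(node, "value", formatValue(v, prop@dtype))
  }
  invisible(node)
}

.sectionToXml <- function(parent, sec) {
  node <- xml2::xml_add_child(parent, "section")
  .xmlAddText(node, "name", sec@name)
  .xmlAddText(node, "type", sec@type)
  .xmlAddText(node, "definition", sec@definition)
  .xmlAddText(node, "reference", sec@reference)
  .xmlAddText(node, "link", sec@link)
  .xmlAddText(node, "include", sec@include)
  .xmlAddText(node, "repository", sec@repository)
  .xmlAddText(node, "id", sec@id)
  for (p in sec@properties) .propertyToXml(node, p)
  for (s in sec@sections) .sectionToXml(node, s)
  invisible(node)
}

.documentToXml <- function(document) {
  root <- xml2::xml_new_root("odML", version = "1.4")
  .xmlAddText(root, "author", document@author)
  .xmlAddText(root, "date", document@date)
  .xmlAddText(root, "version", document@version)
  .xmlAddText(root, "repository", document@repository)
  for (s in document@sections) .sectionToXml(root, s)
  root
}

.childText <- function(node, tag) {
  child <- xml2::xml_find_first(node, paste0("./", tag))
  if (inherits(child, "xml_missing")) character(0) else xml2::xml_text(child)
}

.xmlToProperty <- function(node, registry) {
  dt <- .childText(node, "type")
  if (length(dt)) dt <- resolveDtype(dt, registry)
  vals <- lapply(xml2::xml_find_all(node, "./value"), function(v) {
    coerceValue(xml2::xml_text(v), if (length(dt)) dt else "string", registry)
  })
  unc <- .childText(node, "uncertainty")
  id <- .childText(node, "id")
  odmlProperty(
    name = .childText(node, "name"),
    definition = .childText(node, "definition"),
    values = vals,
    dtype = if (length(dt)) dt else NULL,
    unit = .childText(node, "unit"),
    uncertainty = if (length(unc)) as.numeric(unc) else NULL,
    valueOrigin = .childText(node, "value_origin"),
    reference = .childText(node, "reference"),
    id = if (length(id)) id else NULL,
    registry = registry
  )
}

.xmlToSection <- function(node, registry) {
  id <- .childText(node, "id")
  odmlSection(
    name = .childText(node, "name"),
    type = .childText(node, "type"),
    definition = .childText(node, "definition"),
    reference = .childText(node, "reference"),
    link = .childText(node, "link"),
    include = .childText(node, "include"),
    repository = .childText(node, "repository"),
    id = if (length(id)) id else NULL,
    properties = lapply(xml2::xml_find_all(node, "./property"),
                        .xmlToProperty, registry = registry),
    sections = lapply(xml2::xml_find_all(node, "./section"),
                      .xmlToSection, registry = registry)
  )
}

.xmlToDocument <- function(root, registry) {
  odmlDocument(
    author = .childText(root, "author"),
    date = .childText(root, "date"),
    version = .childText(root, "version"),
    repository = .childText(root, "repository"),
    sections = lapply(xml2::xml_find_all(root, "./section"),
                      .xmlToSection, registry = registry)
  )
}

## ---- JSON / YAML (one mapping mirroring the XML element tree) ----

.dropNull <- function(x) x[!vapply(x, is.null, logical(1))]

.propertyToList <- function(prop) {
  vals <- vapply(prop@values, function(v) formatValue(v, prop@dtype), "")
  .dropNull(list(
    name = prop@name,
    definition = if (length(prop@definition)) prop@definition else NULL,
    type = if (length(prop@dtype)) prop@dtype else NULL,
    unit = if (length(prop@unit)) prop@unit else NULL,
    uncertainty = if (length(prop@uncertainty)) {
      formatValue(prop@uncertainty, "float")
    } else NULL,
    value_origin = if (length(prop@valueOrigin)) prop@valueOrigin else NULL,
    reference = if (length(prop@reference)) prop@reference else NULL,
    id = prop@id,
    values = as.list(vals)
  ))
}

.sectionToList <- function(sec) {
  .dropNull(list(
    name = sec@name,
    type = if (length(sec@type)) sec@type else NULL,
    definition = if (length(sec@definition)) sec@definition else NULL,
    reference = if (length(sec@reference)) sec@reference else NULL,
    link = if (length(sec@link)) sec@link else NULL,
    include = if (length(sec@include)) sec@include else NULL,
    repository = if (length(sec@repository)) sec@repository else NULL,
    id = sec@id,
    properties = lapply(sec@properties, .propertyToList),
    sections = lapply(sec@sections, .sectionToList)
  ))
}

.documentToList <- function(document) {
  list(Document = .dropNull(list(
    version = "1.4",
    author = if (length(document@author)) document@author else NULL,
    date = if (length(document@date)) document@date else NULL,
    document_version = if (length(document@version)) document@version else NULL,
    repository = if (length(document@repository)) document@repository else NULL,
    sections = lapply(document@sections, .sectionToList)
  )))
}

.lstChr <- function(x, key) {
  v <- x[[key]]
  if (is.null(v)) character(0) else as.character(v)
}

.listToProperty <- function(x, registry) {
  dt <- .lstChr(x, "type")
  if (length(dt)) dt <- resolveDtype(dt, registry)
  vals <- lapply(x[["values"]], function(v) {
    coerceValue(as.character(v), if (length(dt)) dt else "string", registry)
  })
  unc <- .lstChr(x, "uncertainty")
  id <- .lstChr(x, "id")
  odmlProperty(
    name = .lstChr(x, "name"),
    definition = .lstChr(x, "definition"),
    values = vals,
    dtype = if (length(dt)) dt else NULL,
    unit = .lstChr(x, "unit"),
    uncertainty = if (length(unc)) as.numeric(unc) else NULL,
    valueOrigin = .lstChr(x, "value_origin"),
    reference = .lstChr(x, "reference"),
    id = if (length(id)) id else NULL,
    registry = registry
  )
}

.listToSection <- function(x, registry) {
  id <- .lstChr(x, "id")
  odmlSection(
    name = .lstChr(x, "name"),
    type = .lstChr(x, "type"),
    definition = .lstChr(x, "definition"),
    reference = .lstChr(x, "reference"),
    link = .lstChr(x, "link"),
    include = .lstChr(x, "include"),
    repository = .lstChr(x, "repository"),
    id = if (length(id)) id else NULL,
    properties = lapply(x[["properties"]], .listToProperty, registry = registry),
    sections = lapply(x[["sections"]], .listToSection, registry = registry)
  )
}

.listToDocument <- function(x, registry) {
  d <- x[["Document"]]
  if (is.null(d)) {
    odmlStop("odmlParseError", "missing top-level 'Document' mapping")
  }
  ver <- .lstChr(d, "version")
  if (length(ver) && !identical(ver, "1.4")) {
    odmlStop("odmlVersionError", "unsupported odML version '%s'", ver)
  }
  odmlDocument(
    author = .lstChr(d, "author"),
    date = .lstChr(d, "date"),
    version = .lstChr(d, "document_version"),
    repository = .lstChr(d, "repository"),
    sections = lapply(d[["sections"]], .listToSection, registry = registry)
  )
}

# Keep YAML scalars as raw text: the dialect stores values as formatted
# strings, so YAML's implicit typing (True -> logical, 5.5 -> numeric) must
# be suppressed.
.yamlTextHandlers <- local({
  keep <- function(x) x
  list(
    "bool#yes" = keep, "bool#no" = keep,
    "int" = keep, "float" = keep,
    "float#nan" = keep, "float#inf" = keep, "float#neginf" = keep
  )
})

## ---- v1.3 upgrade ----

.v13ValueRecord <- function(vnode) {
  textNodes <- xml2::xml_find_all(vnode, "./text()")
  raw <- if (length(textNodes)) {
    trimws(paste(vapply(textNodes, xml2::xml_text, ""), collapse = ""))
  } else ""
  list(
    raw = raw,
    dtype = .childText(vnode, "type"),
    unit = .childText(vnode, "unit"),
    uncertainty = .childText(vnode, "uncertainty")
  )
}

.uniqueAttr <- function(records, field) {
  vals <- unique(unlist(lapply(records, function(r) r[[field]])))
  vals[nzchar(vals)]
}

.v13BuildProperty <- function(name, definition, records, registry) {
  dt <- .uniqueAttr(records, "dtype")
  if (length(dt)) dt <- resolveDtype(dt[1], registry)
  unit <- .uniqueAttr(records, "unit")
  unc <- .uniqueAttr(records, "uncertainty")
  vals <- lapply(records, function(r) {
    coerceValue(r$raw, if (length(dt)) dt else "string", registry)
  })
  odmlProperty(
    name = name,
    definition = definition,
    values = vals,
    dtype = if (length(dt)) dt else NULL,
    unit = if (length(unit)) unit[1] else NULL,
    uncertainty = if (length(unc)) as.numeric(unc[1]) else NULL,
    registry = registry
  )
}

.v13UpgradeProperty <- function(node, path, mode, registry) {
  name <- .childText(node, "name")
  definition <- .childText(node, "definition")
  records <- lapply(xml2::xml_find_all(node, "./value"), .v13ValueRecord)
  attrKey <- vapply(records, function(r) {
    paste(
      if (length(r$dtype)) r$dtype else "",
      if (length(r$unit)) r$unit else "",
      if (length(r$uncertainty)) r$uncertainty else "",
      sep = "\r"
    )
  }, "")
  homogeneous <- length(unique(attrKey)) <= 1 ||
    (length(.uniqueAttr(records, "dtype")) <= 1 &&
     length(.uniqueAttr(records, "unit")) <= 1 &&
     length(.uniqueAttr(records, "uncertainty")) <= 1)
  if (homogeneous) {
    return(list(.v13BuildProperty(name, definition, records, registry)))
  }
  if (identical(mode, "strict")) {
    odmlStop(
      "odmlUpgradeError",
      "property '%s:%s' has values with conflicting dtype/unit/uncertainty",
      path, name
    )
  }
  # lenient: split into suffixed properties, one per attribute combination,
  # preserving value order within each group.
  groups <- split(records, factor(attrKey, levels = unique(attrKey)))
  out <- list()
  for (i in seq_along(groups)) {
    out[[i]] <- .v13BuildProperty(
      paste0(name, "_", i), definition, groups[[i]], registry
    )
  }
  out
}

.v13UpgradeSection <- function(node, parentPath, mode, registry) {
  name <- .childText(node, "name")
  path <- paste0(parentPath, "/", name)
  props <- list()
  for (pnode in xml2::xml_find_all(node, "./property")) {
    props <- c(props, .v13UpgradeProperty(pnode, path, mode, registry))
  }
  odmlSection(
    name = name,
    type = .childText(node, "type"),
    definition = .childText(node, "definition"),
    reference = .childText(node, "reference"),
    link = .childText(node, "link"),
    include = .childText(node, "include"),
    repository = .childText(node, "repository"),
    properties = props,
    sections = lapply(xml2::xml_find_all(node, "./section"),
                      .v13UpgradeSection, parentPath = path,
                      mode = mode, registry = registry)
  )
}

#' Upgrade a legacy v1.3 odML XML tree to the v1.4 model
#'
#' In the v1.3 model each Property holds one or more Value entities, each
#' carrying its own dtype/unit/uncertainty. The v1.4 model stores one value
#' list per property with the value-level attributes shared. The upgrade
#' collapses each property's values into one list; entities gain freshly
#' minted UUIDs (v1.3 files carry none). When the values of one property
#' disagree on dtype, unit or uncertainty, strict mode raises an upgrade
#' error naming the property; lenient mode splits the property into
#' suffixed properties (\code{name_1}, \code{name_2}, ...), one per
#' attribute combination. The total number of values is conserved.
#'
#' @param x An \code{xml2} document or node whose root is a v1.3
#'   \code{odML} element.
#' @param mode \code{"strict"} (default) or \code{"lenient"}.
#' @param registry Data-type registry for value coercion.
#' @return An \linkS4class{odmlDocument}.
#' @export
upgradeV13 <- function(x, mode = c("strict", "lenient"),
                       registry = dtypeRegistry()) {
  mode <- match.arg(mode)
  root <- xml2::xml_root(x)
  odmlDocument(
    author = .childText(root, "author"),
    date = .childText(root, "date"),
    version = .childText(root, "version"),
    repository = .childText(root, "repository"),
    sections = lapply(xml2::xml_find_all(root, "./section"),
                      .v13UpgradeSection, parentPath = "",
                      mode = mode, registry = registry)
  )
}

## ---- public read/write ----

#' Read a hierarchical odML file
#'
#' Reads XML (canonical), JSON or YAML serializations into an
#' \linkS4class{odmlDocument}. Legacy v1.3 XML files are transparently
#' upgraded to the v1.4 model (see \code{\link{upgradeV13}}). The returned
#' document passes \code{\link{validateDocument}}.
#'
#' @param path File to read.
#' @param format \code{"auto"} (detect by extension, then by content),
#'   \code{"xml"}, \code{"json"} or \code{"yaml"}.
#' @param upgradeMode Conflict handling for v1.3 files, passed to
#'   \code{\link{upgradeV13}}.
#' @param registry Data-type registry for value coercion.
#' @return An \linkS4class{odmlDocument}.
#' @seealso \code{\link{writeOdml}}
#' @export
readOdml <- function(path, format = "auto",
                     upgradeMode = c("strict", "lenient"),
                     registry = dtypeRegistry()) {
  upgradeMode <- match.arg(upgradeMode)
  if (!file.exists(path)) {
    odmlStop("odmlIoError", "file not found: %s", path)
  }
  fmt <- .resolveFormat(path, format)
  doc <- switch(fmt,
    xml = {
      x <- xml2::read_xml(path)
      root <- xml2::xml_root(x)
      if (!identical(xml2::xml_name(root), "odML")) {
        odmlStop("odmlParseError", "root element is '%s', expected 'odML'",
                 xml2::xml_name(root))
      }
      ver <- xml2::xml_attr(root, "version")
      if (is.na(ver)) {
        odmlStop("odmlVersionError", "odML root carries no version attribute")
      } else if (identical(ver, "1.4")) {
        .xmlToDocument(root, registry)
      } else if (identical(ver, "1.3")) {
        upgradeV13(x, mode = upgradeMode, registry = registry)
      } else {
        odmlStop("odmlVersionError", "unknown odML version '%s'", ver)
      }
    },
    json = .listToDocument(
      jsonlite::read_json(path, simplifyVector = FALSE), registry
    ),
    yaml = .listToDocument(
      yaml::read_yaml(path, handlers = .yamlTextHandlers), registry
    )
  )
  .stopIfInvalid(doc, registry)
  doc
}

#' Write a hierarchical odML file
#'
#' Serializes a document to XML (canonical, with \code{version="1.4"} on
#' the root), JSON or YAML. The file re-reads with \code{\link{readOdml}}
#' to a document equal to the input, including UUIDs, attributes and the
#' ordering of sections, properties and values. All files are UTF-8.
#'
#' @param document An \linkS4class{odmlDocument}; must pass
#'   \code{\link{validateDocument}}.
#' @param path Output file.
#' @param format \code{"auto"} (by extension), \code{"xml"}, \code{"json"}
#'   or \code{"yaml"}.
#' @param registry Data-type registry used for validation and formatting.
#' @return Invisibly, \code{path}.
#' @export
writeOdml <- function(document, path, format = "auto",
                      registry = dtypeRegistry()) {
  .stopIfInvalid(document, registry)
  fmt <- if (identical(format, "auto")) {
    f <- .formatFromPath(path)
    if (is.na(f)) "xml" else f
  } else {
    if (!format %in% .FORMATS) {
      odmlStop("odmlFormatError", "unknown serialization format '%s'", format)
    }
    format
  }
  switch(fmt,
    xml = xml2::write_xml(.documentToXml(document), path),
    json = jsonlite::write_json(
      .documentToList(document), path,
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    ),
    yaml = yaml::write_yaml(.documentToList(document), path)
  )
  invisible(path)
}
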