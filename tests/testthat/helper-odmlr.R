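# Shared helpers: temp paths, independent oracles, small builders.

tmpPath <- function(ext) tempfile(fileext = paste0(".", ext))

expect_docs_equal <- function(a, b, ignoreIds = FALSE, ignoreLossy = FALSE) {
  expect_true(odmlEquals(a, b, ignoreIds = ignoreIds,
                         ignoreLossy = ignoreLossy))
}

# A small fully-specified document used across unit tests.
miniDocument <- function() {
  odmlDocument(
    author = "Alice", date = "2000-01-03", version = "0.1",
    sections = list(
      odmlSection("Setup", type = "hardware", properties = list(
        odmlProperty("Amplifier", values = list("NeuroAmp"),
                     dtype = "string"),
        odmlProperty("Gain", values = list(1000L), dtype = "int")
      ), sections = list(
        odmlSection("Electrode", type = "hardware", properties = list(
          odmlProperty("Impedance", values = list(1.2, 1.5),
                       dtype = "float", unit = "mm", uncertainty = 0.1)
        ))
      ))
    )
  )
}

# Independent filter oracle: evaluates the spec over flattened rows,
# grouped per property, without touching filterDocument() internals.
bruteForceSurvivors <- function(document, spec) {
  rows <- flattenDocument(document)$rows
  if (!nrow(rows)) return(character(0))
  key <- paste(rows$path_to_section, rows$property_name, sep = "\r")
  groups <- split(seq_len(nrow(rows)), factor(key, levels = unique(key)))
  recOf <- function(idx) {
    g <- rows[idx, , drop = FALSE]
    vals <- g$value[!is.na(g$value)]
    vals[vals == "\"\""] <- ""
    list(
      path = g$path_to_section[1],
      section_name = g$section_name[1],
      section_type = g$section_type[1],
      property_name = g$property_name[1],
      values = vals,
      data_unit = g$data_unit[1],
      odml_data_type = g$odml_data_type[1],
      value_count = length(vals)
    )
  }
  evalCmp <- function(cmp, rec) {
    if (cmp$op == "is_empty") {
      if (cmp$field %in% c("value", "value_count")) {
        return(rec$value_count == 0)
      }
      f <- rec[[cmp$field]]
      return(is.na(f) || !nzchar(f))
    }
    target <- if (cmp$field == "value") rec$values
      else if (cmp$field == "value_count") as.character(rec$value_count)
      else rec[[cmp$field]]
    if (cmp$field == "value" && !length(target)) return(FALSE)
    if (length(target) == 1 && is.na(target)) return(FALSE)
    op <- as.character(cmp$operand)
    hit <- switch(cmp$op,
      equals = if (cmp$field == "value_count") {
        rec$value_count == as.numeric(op)
      } else target == op,
      contains = grepl(op, target, fixed = TRUE),
      matches = grepl(op, target)
    )
    any(hit)
  }
  evalStep <- function(step, rec) {
    hits <- vapply(step$comparisons, evalCmp, logical(1), rec = rec)
    if (!is.null(step$custom)) hits <- c(hits, isTRUE(step$custom(rec)))
    m <- if (identical(step$combine, "all")) all(hits) else any(hits)
    if (identical(step$mode, "keep")) m else !m
  }
  surviving <- names(groups)
  for (step in spec$steps) {
    surviving <- Filter(function(k) evalStep(step, recOf(groups[[k]])),
                        surviving)
  }
  out <- unlist(lapply(surviving, function(k) {
    gsub("\r", ":", k, fixed = TRUE)
  }))
  if (is.null(out)) character(0) else out
}

# Property keys ("path:name") present in a document.
propertyKeys <- function(document) {
  recs <- flattenDocument(document)$rows
  if (!nrow(recs)) return(character(0))
  unique(paste(recs$path_to_section, recs$property_name, sep = ":"))
}

# Draws a random but meaningful filter spec for a document: operands are
# sampled from the document's own field values so steps are not vacuous.
randomFilterSpec <- function(document, nSteps = NULL) {
  rows <- flattenDocument(document)$rows
  fields <- c("path", "section_name", "section_type", "property_name",
              "value", "data_unit", "odml_data_type", "value_count")
  colOf <- c(
    path = "path_to_section", section_name = "section_name",
    section_type = "section_type", property_name = "property_name",
    value = "value", data_unit = "data_unit",
    odml_data_type = "odml_data_type"
  )
  if (is.null(nSteps)) nSteps <- sample(1:3, 1)
  steps <- lapply(seq_len(nSteps), function(i) {
    nCmp <- sample(1:2, 1)
    cmps <- lapply(seq_len(nCmp), function(j) {
      f <- sample(fields, 1)
      op <- sample(c("equals", "contains", "matches", "is_empty"), 1)
      operand <- NULL
      if (op != "is_empty") {
        operand <- if (f == "value_count") {
          sample(0:3, 1)
        } else {
          pool <- rows[[colOf[[f]]]]
          pool <- pool[!is.na(pool)]
          if (!length(pool)) "zzz" else {
            v <- sample(pool, 1)
            if (op == "matches") {
              # escape so arbitrary cell text is a literal pattern
              v <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", v)
            }
            if (op == "contains" && nchar(v) > 2) {
              v <- substr(v, 1, max(1, nchar(v) - 1))
            }
            v
          }
        }
      }
      comparison(f, op, operand)
    })
    filterStep(
      mode = sample(c("keep", "reject"), 1),
      comparisons = cmps,
      combine = sample(c("all", "any"), 1)
    )
  })
  filterSpec(steps)
}

# Rename top-level sections so two generated documents merge disjointly.
suffixTopSections <- function(document, suffix) {
  document@sections <- lapply(document@sections, function(s) {
    s@name <- paste0(s@name, suffix)
    s
  })
  document
}

# Multiset of (property path, rendered value) pairs, for conservation laws.
valueMultiset <- function(document) {
  rows <- flattenDocument(document)$rows
  rows <- rows[!is.na(rows$value), , drop = FALSE]
  sort(paste(rows$path_to_section, rows$property_name, rows$value,
             sep = "\r"))
}
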