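test_that("every hierarchical format round-trips documents exactly", {
  docs <- list(odmlDocument(), miniDocument(),
               buildSubjectDocument("enriched"),
               randomDocument(7, tabularSafe = FALSE))
  for (doc in docs) {
    for (fmt in c("xml", "json", "yaml")) {
      p <- tmpPath(switch(fmt, xml = "odml", fmt))
      writeOdml(doc, p, fmt)
      expect_docs_equal(doc, readOdml(p, fmt))
    }
  }
})

test_that("format auto-detection works by extension and by content", {
  doc <- miniDocument()
  for (ext in c("odml", "xml", "json", "yaml", "yml")) {
    p <- tmpPath(ext)
    writeOdml(doc, p)
    expect_docs_equal(doc, readOdml(p))
  }
  # unknown extension: sniffed from content
  p <- tmpPath("dat")
  writeOdml(doc, p, "json")
  expect_docs_equal(doc, readOdml(p))
})

test_that("one document written in all three formats reads back identically", {
  for (seed in c(1, 2, 3)) {
    doc <- randomDocument(seed, tabularSafe = FALSE)
    reads <- lapply(c("xml", "json", "yaml"), function(fmt) {
      p <- tmpPath(fmt)
      writeOdml(doc, p, fmt)
      readOdml(p, fmt)
    })
    expect_docs_equal(reads[[1]], reads[[2]])
    expect_docs_equal(reads[[2]], reads[[3]])
  }
})

test_that("writing an invalid document fails with the violation list", {
  doc <- odmlDocument(sections = list(
    odmlSection("S", properties = list(
      odmlProperty("x", values = list("nope"), dtype = "int")
    ))
  ))
  expect_error(writeOdml(doc, tmpPath("odml")), class = "odmlValidationError")
})

test_that("version and parse errors are reported distinctly", {
  p <- tmpPath("odml")
  writeLines('<odML version="9.9"><section><name>S</name></section></odML>', p)
  expect_error(readOdml(p), class = "odmlVersionError")
  writeLines("<odML><section><name>S</name></section></odML>", p)
  expect_error(readOdml(p), class = "odmlVersionError")
  writeLines("<nodml/>", p)
  expect_error(readOdml(p), class = "odmlParseError")
  writeLines("<odML version=\"1.4\"><section>", p)
  expect_error(readOdml(p))
  expect_error(readOdml(tmpPath("odml")), class = "odmlIoError")
})

test_that("v1.3 value entities collapse into the property value list", {
  v13 <- paste0(
    '<odML version="1.3"><section><name>S</name><type>t</type>',
    '<property><name>Weight</name>',
    '<value>5.0<unit>g</unit><type>float</type></value>',
    '<value>5.5<unit>g</unit></value></property></section></odML>'
  )
  up <- upgradeV13(xml2::read_xml(v13))
  p <- findProperty(up, "/S", "Weight")
  expect_identical(p@values, list(5.0, 5.5))
  expect_identical(p@unit, "g")
  expect_identical(p@dtype, "float")
  expect_identical(nrow(validateDocument(up)), 0L)
})

test_that("v1.3 files load transparently through readOdml", {
  p <- system.file("extdata", "scoresheet_v13.xml", package = "odmlr")
  doc <- readOdml(p)
  expect_identical(doc@author, "Alice")
  w <- findProperty(doc, "/Subject/Scores_2000-01-01", "Weight")
  expect_identical(w@values, list(5.0, 5.5))
  expect_identical(
    findProperty(doc, "/Subject/Scores_2000-01-01", "Date")@values[[1]],
    as.Date("2000-01-01")
  )
})

test_that("conflicting v1.3 value attributes error in strict mode, split in lenient", {
  v13 <- paste0(
    '<odML version="1.3"><section><name>S</name>',
    '<property><name>m</name>',
    '<value>5.0<unit>g</unit><type>float</type></value>',
    '<value>6.0<unit>kg</unit><type>float</type></value>',
    '</property></section></odML>'
  )
  x <- xml2::read_xml(v13)
  err <- tryCatch(upgradeV13(x), error = function(e) e)
  expect_s3_class(err, "odmlUpgradeError")
  expect_match(conditionMessage(err), "/S:m")
  up <- upgradeV13(x, mode = "lenient")
  sec <- findSection(up, "/S")
  expect_identical(vapply(properties(sec), odmlName, ""), c("m_1", "m_2"))
  expect_identical(findProperty(up, "/S", "m_1")@unit, "g")
  expect_identical(findProperty(up, "/S", "m_2")@unit, "kg")
})

test_that("v1.3 upgrade conserves the total value count", {
  for (seed in 1:5) {
    doc <- randomDocument(seed, dtypes = c("int", "float", "string"))
    # render the generated document as a v1.3 tree (one Value element per
    # value, attributes repeated) and upgrade it back
    toV13 <- function(document) {
      esc <- function(x) {
        x <- gsub("&", "&amp;", x, fixed = TRUE)
        x <- gsub("<", "&lt;", x, fixed = TRUE)
        gsub(">", "&gt;", x, fixed = TRUE)
      }
      propXml <- function(p) {
        vals <- vapply(p@values, function(v) {
          attrs <- paste0(
            if (length(p@unit)) paste0("<unit>", esc(p@unit), "</unit>") else "",
            if (length(p@dtype)) paste0("<type>", p@dtype, "</type>") else ""
          )
          paste0("<value>", esc(formatValue(v, p@dtype)), attrs, "</value>")
        }, "")
        paste0("<property><name>", esc(p@name), "</name>",
               paste(vals, collapse = ""), "</property>")
      }
      secXml <- function(s) {
        paste0(
          "<section><name>", esc(s@name), "</name>",
          paste(vapply(s@properties, propXml, ""), collapse = ""),
          paste(vapply(s@sections, secXml, ""), collapse = ""),
          "</section>"
        )
      }
      paste0('<odML version="1.3">',
             paste(vapply(document@sections, secXml, ""), collapse = ""),
             "</odML>")
    }
    up <- upgradeV13(xml2::read_xml(toV13(doc)))
    expect_identical(documentCounts(up)["values"],
                     documentCounts(doc)["values"])
  }
})

test_that("a v1.3 document without properties upgrades structurally unchanged", {
  v13 <- paste0(
    '<odML version="1.3"><author>Bob</author>',
    '<section><name>A</name><type>x</type>',
    '<section><name>B</name></section></section></odML>'
  )
  up <- upgradeV13(xml2::read_xml(v13))
  expect_identical(up@author, "Bob")
  expect_identical(odmlName(sections(up)[[1]]), "A")
  expect_identical(odmlName(sections(sections(up)[[1]])[[1]]), "B")
  expect_identical(unname(documentCounts(up)), c(2L, 0L, 0L))
})

test_that("the shipped fixture corpus reads equal across formats", {
  base <- system.file("extdata", package = "odmlr")
  xml <- readOdml(file.path(base, "subject_enriched.odml"))
  json <- readOdml(file.path(base, "subject_enriched.json"))
  yaml <- readOdml(file.path(base, "subject_enriched.yaml"))
  csv <- readOdmlCsv(file.path(base, "subject_enriched.csv"))
  expect_docs_equal(xml, json)
  expect_docs_equal(xml, yaml)
  expect_docs_equal(xml, csv, ignoreIds = TRUE, ignoreLossy = TRUE)
  expect_docs_equal(xml, buildSubjectDocument("enriched"), ignoreIds = TRUE)
})
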