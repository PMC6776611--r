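test_that("csv files carry the document row, headers and one line per row", {
  doc <- buildSubjectDocument("enriched")
  p <- tmpPath("csv")
  writeOdmlCsv(doc, p)
  lines <- readLines(p)
  expect_match(lines[1], '^"Document Information","author"')
  expect_match(lines[2], '"Path to Section","Section Name"')
  expect_identical(length(lines), 2L + nrow(flattenDocument(doc)$rows))
  expect_docs_equal(readOdmlCsv(p), doc, ignoreIds = TRUE,
                    ignoreLossy = TRUE)
})

test_that("an empty document writes document row and header line only", {
  p <- tmpPath("csv")
  writeOdmlCsv(odmlDocument(author = "Bob"), p)
  expect_identical(length(readLines(p)), 2L)
  back <- readOdmlCsv(p)
  expect_identical(back@author, "Bob")
  expect_length(sections(back), 0)
})

test_that("custom headers render and are required for reading back", {
  lay <- tableLayout(
    columns = c("path_to_section", "property_name", "value", "data_unit",
                "odml_data_type"),
    headerMap = c(path_to_section = "Section", property_name = "Measure",
                  data_unit = "Unit", odml_data_type = "Type")
  )
  doc <- miniDocument()
  p <- tmpPath("csv")
  writeOdmlCsv(doc, p, lay)
  expect_match(readLines(p)[2],
               '^"Section","Measure","Value","Unit","Type"(,"")*$')
  err <- tryCatch(readOdmlCsv(p), error = function(e) e)
  expect_s3_class(err, "odmlHeaderError")
  expect_match(conditionMessage(err), "Measure")
  back <- readOdmlCsv(p, lay)
  expect_identical(
    findProperty(back, "/Setup/Electrode", "Impedance")@unit, "mm")
})

test_that("columns are associated by header name, not by position", {
  doc <- miniDocument()
  p <- tmpPath("csv")
  writeOdmlCsv(doc, p)
  grid <- as.matrix(utils::read.csv(p, header = FALSE,
                                    colClasses = "character"))
  dimnames(grid) <- NULL
  perm <- sample(ncol(grid))
  permuted <- grid
  permuted[2:nrow(grid), ] <- grid[2:nrow(grid), perm]
  p2 <- tmpPath("csv")
  con <- file(p2, "wb")
  utils::write.table(permuted, con, sep = ",", quote = TRUE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  close(con)
  expect_docs_equal(readOdmlCsv(p2), readOdmlCsv(p), ignoreIds = TRUE)
})

test_that("xlsx and csv carry identical logical content", {
  for (seed in 1:5) {
    doc <- randomDocument(seed)
    pc <- tmpPath("csv"); px <- tmpPath("xlsx")
    writeOdmlCsv(doc, pc)
    writeOdmlXlsx(doc, px)
    expect_docs_equal(readOdmlCsv(pc), readOdmlXlsx(px), ignoreIds = TRUE)
    expect_docs_equal(readOdmlXlsx(px), doc, ignoreIds = TRUE,
                      ignoreLossy = TRUE)
  }
})

test_that("compaction on or off yields the same parsed document", {
  doc <- randomDocument(11)
  for (cls in c("csv", "xlsx")) {
    pPlain <- tmpPath(cls); pComp <- tmpPath(cls)
    writer <- if (cls == "csv") writeOdmlCsv else writeOdmlXlsx
    reader <- if (cls == "csv") readOdmlCsv else readOdmlXlsx
    writer(doc, pPlain, tableLayout(compaction = FALSE))
    writer(doc, pComp, tableLayout(compaction = TRUE))
    expect_docs_equal(reader(pPlain), reader(pComp), ignoreIds = TRUE)
  }
})

test_that("xlsx styling highlights defaults and missing values", {
  doc <- odmlDocument(sections = list(
    odmlSection("S", properties = list(
      odmlProperty("present", values = list(7.5), dtype = "float"),
      odmlProperty("atDefault", values = list(0.0), dtype = "float"),
      odmlProperty("missing", dtype = "float")
    ))
  ))
  style <- styleSpec()
  p <- tmpPath("xlsx")
  writeOdmlXlsx(doc, p, tableLayout(style = style))
  tmp <- tempfile(); dir.create(tmp)
  zip::unzip(p, exdir = tmp)
  styles <- paste(readLines(file.path(tmp, "xl", "styles.xml"),
                            warn = FALSE), collapse = "")
  expect_match(styles, "FFFF0000")            # missing-value red
  expect_match(styles, paste0("FF", style@defaultValueFill))
  sheet <- paste(readLines(file.path(tmp, "xl", "worksheets", "sheet1.xml"),
                           warn = FALSE), collapse = "")
  expect_match(sheet, 'xml:space="preserve"')
  unlink(tmp, recursive = TRUE)
  # an unstyled document shows no solid fills at all
  p2 <- tmpPath("xlsx")
  writeOdmlXlsx(doc, p2, tableLayout())
  tmp2 <- tempfile(); dir.create(tmp2)
  zip::unzip(p2, exdir = tmp2)
  styles2 <- paste(readLines(file.path(tmp2, "xl", "styles.xml"),
                             warn = FALSE), collapse = "")
  expect_false(grepl("solid", styles2))
  unlink(tmp2, recursive = TRUE)
})

test_that("styling never affects parsing (fuzzed fills)", {
  withr::with_seed(99, {
    for (k in 1:5) {
      doc <- randomDocument(k + 40)
      randomStyle <- styleSpec(
        sectionRowColors = sprintf("%06X", sample(0:16777215, 2)),
        propertyRowColors = sprintf("%06X", sample(0:16777215, 2)),
        defaultValueFill = sprintf("%06X", sample(0:16777215, 1)),
        missingValueFill = sprintf("%06X", sample(0:16777215, 1)),
        headerFill = sprintf("%06X", sample(0:16777215, 1))
      )
      pStyled <- tmpPath("xlsx"); pPlain <- tmpPath("xlsx")
      writeOdmlXlsx(doc, pStyled, tableLayout(style = randomStyle))
      writeOdmlXlsx(doc, pPlain, tableLayout())
      expect_docs_equal(readOdmlXlsx(pStyled), readOdmlXlsx(pPlain),
                        ignoreIds = TRUE)
    }
  })
})

test_that("readxl independently confirms the written xlsx grid", {
  doc <- buildSubjectDocument("enriched")
  p <- tmpPath("xlsx")
  writeOdmlXlsx(doc, p, tableLayout(style = styleSpec()))
  ours <- readCompareGrid(p)
  theirs <- suppressMessages(as.matrix(readxl::read_xlsx(
    p, col_names = FALSE, col_types = "text"
  )))
  dimnames(theirs) <- NULL
  theirs[is.na(theirs)] <- ""
  expect_identical(dim(ours), dim(theirs))
  expect_identical(ours, theirs)
})

test_that("workbooks written by another tool (openpyxl) read back fine", {
  p <- tmpPath("xlsx")
  script <- sprintf(paste0(
    "from openpyxl import Workbook\n",
    "wb = Workbook(); ws = wb.active\n",
    "ws.append(['Document Information','author','Alice','date','','version','','repository',''])\n",
    "ws.append(['Path to Section','Property Name','Value','odML Data Type'])\n",
    "ws.append(['/Subject','Weight','5.5','float'])\n",
    "wb.save(%s)\n"
  ), shQuote(p))
  res <- system2("python", c("-c", shQuote(script)))
  expect_identical(res, 0L)
  doc <- readOdmlXlsx(p)
  expect_identical(doc@author, "Alice")
  expect_identical(findProperty(doc, "/Subject", "Weight")@values, list(5.5))
})

test_that("layout configs round-trip through their text form", {
  lay <- tableLayout(
    columns = c("path_to_section", "property_name", "value", "data_unit"),
    headerMap = c(path_to_section = "Section", property_name = "Measure"),
    compaction = TRUE
  )
  p <- tmpPath("cfg")
  writeLayoutConfig(lay, p)
  back <- readLayoutConfig(p)
  expect_identical(back@columns, lay@columns)
  expect_identical(back@headerMap[back@columns], lay@headerMap[lay@columns])
  expect_identical(back@compaction, TRUE)
  expect_error(readLayoutConfig(tmpPath("cfg")), class = "odmlIoError")
})

test_that("layouts must keep the mandatory columns", {
  expect_error(tableLayout(columns = c("path_to_section", "value")),
               "property_name")
  expect_error(
    tableLayout(columns = c("path_to_section", "property_name", "value"),
                headerMap = c(path_to_section = "Same",
                              property_name = "Same")),
    "injective"
  )
})
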