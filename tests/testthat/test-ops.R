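test_that("templates keep designer defaults and otherwise empty values", {
  for (ext in c("csv", "xlsx")) {
    p <- tmpPath(ext)
    createTemplate(p, skeleton = buildScoresheetTemplate())
    back <- if (ext == "csv") readOdmlCsv(p) else readOdmlXlsx(p)
    sec <- "/Subject/Scores_YYYY-MM-DD"
    expect_identical(findProperty(back, sec, "Experimenter")@values,
                     list("Alice"))
    expect_identical(findProperty(back, sec, "Weight")@unit, "g")
    expect_length(findProperty(back, sec, "Weight")@values, 0)
    expect_length(findProperty(back, sec, "Date")@values, 0)
    expect_length(findProperty(back, sec, "Comment")@values, 0)
  }
})

test_that("a skeleton-less template writes one generic placeholder row", {
  p <- tmpPath("csv")
  createTemplate(p)
  lines <- readLines(p)
  expect_identical(length(lines), 3L)
  back <- readOdmlCsv(p)
  expect_identical(unname(documentCounts(back)), c(1L, 1L, 0L))
  expect_error(createTemplate(tmpPath("pdf")), class = "odmlUsageError")
})

test_that("merging adds a second recording day to the subject document", {
  day1 <- odmlDocument(sections = list(
    odmlSection("Subject", type = "subject", sections = list(
      sections(sections(buildSubjectDocument("enriched"))[[1]])[[1]]
    ))
  ))
  day2 <- odmlDocument(sections = list(
    odmlSection("Subject", sections = list(
      sections(sections(buildSubjectDocument("enriched"))[[1]])[[2]]
    ))
  ))
  merged <- mergeDocuments(day1, day2)
  subj <- findSection(merged, "/Subject")
  expect_length(sections(subj), 2)
  expect_identical(subj@type, "subject")   # target attribute kept
  expect_identical(subj@id, day1@sections[[1]]@id)
  expect_docs_equal(merged, buildSubjectDocument("enriched"),
                    ignoreIds = TRUE)
})

test_that("merge with an empty document is the identity", {
  for (seed in 1:5) {
    d <- randomDocument(seed)
    expect_docs_equal(mergeDocuments(d, odmlDocument()), d)
    expect_docs_equal(mergeDocuments(odmlDocument(), d), d)
  }
})

test_that("merge under overwrite is idempotent", {
  for (seed in 1:5) {
    d <- randomDocument(seed)
    expect_docs_equal(mergeDocuments(d, d, overwriteValues = TRUE), d)
  }
})

test_that("append-mode merge conserves the value multiset per property", {
  for (seed in 1:5) {
    d <- randomDocument(seed)
    # self-merge doubles every property's values
    doubled <- mergeDocuments(d, d)
    expect_identical(valueMultiset(doubled),
                     sort(c(valueMultiset(d), valueMultiset(d))))
    # disjoint merge is the union
    other <- suffixTopSections(randomDocument(seed + 100), "_b")
    union <- mergeDocuments(d, other)
    expect_identical(valueMultiset(union),
                     sort(c(valueMultiset(d), valueMultiset(other))))
  }
})

test_that("append-mode merge rejects conflicting value attributes", {
  mk <- function(unit) odmlDocument(sections = list(
    odmlSection("S", properties = list(
      odmlProperty("w", values = list(1.0), dtype = "float", unit = unit)
    ))
  ))
  err <- tryCatch(mergeDocuments(mk("g"), mk("kg")), error = function(e) e)
  expect_s3_class(err, "odmlMergeError")
  expect_match(conditionMessage(err), "/S:w")
  # overwrite mode resolves the conflict toward the source
  res <- mergeDocuments(mk("g"), mk("kg"), overwriteValues = TRUE)
  expect_identical(findProperty(res, "/S", "w")@unit, "kg")
})

test_that("overwrite replaces values, append extends them", {
  base <- odmlDocument(sections = list(
    odmlSection("S", properties = list(
      odmlProperty("c", values = list("old"), dtype = "text")
    ))
  ))
  edit <- odmlDocument(sections = list(
    odmlSection("S", properties = list(
      odmlProperty("c", values = list("new"), dtype = "text")
    ))
  ))
  expect_identical(
    findProperty(mergeDocuments(base, edit, TRUE), "/S", "c")@values,
    list("new")
  )
  expect_identical(
    findProperty(mergeDocuments(base, edit, FALSE), "/S", "c")@values,
    list("old", "new")
  )
})

test_that("the empty-value filter extracts exactly the unfilled properties", {
  pre <- buildSubjectDocument("pre_enrichment")
  spec <- filterSpec(filterStep("keep", list(
    comparison("value_count", "equals", 0)
  )))
  empt <- filterDocument(pre, spec)
  expect_identical(unname(documentCounts(empt)["properties"]), 2L)
  keys <- propertyKeys(empt)
  expect_setequal(keys, c("/Subject/Scores_2000-01-01:Comment",
                          "/Subject/Scores_2000-01-02:Comment"))
  # ancestors survive with attributes copied, input unchanged
  expect_identical(findSection(empt, "/Subject")@type, "subject")
  expect_identical(unname(documentCounts(pre)["properties"]), 8L)
  # on the enriched document nothing is empty
  expect_identical(
    unname(documentCounts(
      filterDocument(buildSubjectDocument("enriched"), spec)
    )["properties"]), 0L)
})

test_that("an always-true keep step returns the input minus property-less sections", {
  doc <- randomDocument(21)
  spec <- filterSpec(filterStep("keep", custom = function(rec) TRUE))
  expect_docs_equal(filterDocument(doc, spec), doc)
})

test_that("filtering matches the brute-force oracle on random specs", {
  withr::with_seed(123, {
    for (k in 1:20) {
      doc <- randomDocument(k + 300)
      spec <- randomFilterSpec(doc)
      got <- propertyKeys(filterDocument(doc, spec))
      want <- bruteForceSurvivors(doc, spec)
      expect_setequal(got, want)
    }
  })
})

test_that("filter steps compose sequentially (keep intersects, reject subtracts)", {
  doc <- randomDocument(31)
  s1 <- filterStep("keep", list(comparison("odml_data_type", "equals",
                                           "float")))
  s2 <- filterStep("reject", list(comparison("value_count", "equals", 0)))
  once <- filterDocument(doc, filterSpec(s1, s2))
  twice <- filterDocument(filterDocument(doc, filterSpec(s1)),
                          filterSpec(s2))
  expect_docs_equal(once, twice)
})

test_that("malformed filter specifications are rejected", {
  expect_error(comparison("colour", "equals", "red"),
               class = "odmlFilterSpecError")
  expect_error(comparison("value", "approximates", "x"),
               class = "odmlFilterSpecError")
  expect_error(comparison("value", "equals"),
               class = "odmlFilterSpecError")
  expect_error(filterStep("keep"), class = "odmlFilterSpecError")
  expect_error(filterSpec(), class = "odmlFilterSpecError")
  expect_error(filterDocument(miniDocument(), list()),
               class = "odmlFilterSpecError")
})

test_that("custom predicates participate in filtering", {
  doc <- miniDocument()
  spec <- filterSpec(filterStep(
    "keep", custom = function(rec) rec$value_count >= 2
  ))
  expect_identical(propertyKeys(filterDocument(doc, spec)),
                   "/Setup/Electrode:Impedance")
})

test_that("the filtered-edit-merge cycle restores a fully valued document", {
  pre <- buildSubjectDocument("pre_enrichment")
  spec <- filterSpec(filterStep("keep", list(
    comparison("value_count", "equals", 0)
  )))
  subset <- filterDocument(pre, spec)
  # the experimenter edits the two empty comment cells in the table form
  p <- tmpPath("csv")
  writeOdmlCsv(subset, p)
  grid <- as.matrix(utils::read.csv(p, header = FALSE,
                                    colClasses = "character"))
  dimnames(grid) <- NULL
  valCol <- which(grid[2, ] == "Value")
  grid[3, valCol] <- "Blood sample was taken [...]"
  grid[4, valCol] <- "Small scratch at the right ear"
  con <- file(p, "wb")
  utils::write.table(grid, con, sep = ",", quote = TRUE, row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  close(con)
  edited <- readOdmlCsv(p)
  post <- mergeDocuments(pre, edited, overwriteValues = TRUE)
  expect_docs_equal(post, buildSubjectDocument("enriched"), ignoreIds = TRUE)
  # non-filtered content untouched, including UUIDs
  expect_identical(
    findProperty(post, "/Subject/Scores_2000-01-01", "Weight")@id,
    findProperty(pre, "/Subject/Scores_2000-01-01", "Weight")@id
  )
})

test_that("the comparison table reproduces the reference overview", {
  tab <- compareSections(
    buildSubjectDocument("enriched"),
    c("Date", "Weight", "Experimenter", "Comment"), "Scores_*"
  )
  grid <- rbind(c("", tab@colLabels), cbind(tab@rowLabels, tab@cells))
  expect_identical(grid, referenceCompareGrid())
})

test_that("every compare cell equals a direct tree lookup", {
  doc <- randomDocument(55)
  secs <- sections(sections(doc)[[1]])
  allProps <- unique(unlist(lapply(
    flattenDocument(doc)$rows$property_name, identity
  )))
  tab <- compareSections(doc, allProps, "sec_*")
  for (j in seq_along(tab@colLabels)) {
    for (i in seq_along(tab@rowLabels)) {
      paths <- flattenDocument(doc)$rows
      hit <- paths[paths$section_name == tab@colLabels[j] &
                   paths$property_name == tab@rowLabels[i], , drop = FALSE]
      vals <- if (nrow(hit)) hit$value[!is.na(hit$value)] else character(0)
      if (!length(vals)) {
        expect_identical(tab@cells[i, j], "")
      } else {
        unit <- hit$data_unit[1]
        if (!is.na(unit)) vals <- paste0(vals, unit)
        expect_identical(tab@cells[i, j], paste(vals, collapse = ", "))
      }
    }
  }
})

test_that("multi-value cells join with a comma and per-value units", {
  doc <- odmlDocument(sections = list(
    odmlSection("Scores_X", properties = list(
      odmlProperty("Experimenter", values = list("Alice", "Bob"),
                   dtype = "string"),
      odmlProperty("Weight", values = list(5.0, 5.5), dtype = "float",
                   unit = "g")
    ))
  ))
  tab <- compareSections(doc, c("Experimenter", "Weight"), "Scores_*")
  expect_identical(tab@cells[1, 1], "Alice, Bob")
  expect_identical(tab@cells[2, 1], "5.0g, 5.5g")
})

test_that("compare spec errors and the empty-selector case behave", {
  doc <- buildSubjectDocument("enriched")
  expect_error(compareSections(doc, character(0)),
               class = "odmlCompareSpecError")
  expect_error(compareSections(doc, c("Date", "Date")),
               class = "odmlCompareSpecError")
  tab <- compareSections(doc, "Date", "NoSuchSection_*")
  expect_identical(ncol(tab@cells), 0L)
  rowsTab <- compareSections(doc, c("Date", "Weight"), "Scores_*",
                             orientation = "sections-as-rows")
  expect_identical(rowsTab@rowLabels,
                   c("Scores_2000-01-01", "Scores_2000-01-02"))
  expect_identical(rowsTab@cells[1, 2], "5.0g")
})

test_that("comparison tables write identical grids to csv and xlsx", {
  tab <- compareSections(
    buildSubjectDocument("enriched"),
    c("Date", "Weight", "Experimenter", "Comment"), "Scores_*"
  )
  pc <- tmpPath("csv"); px <- tmpPath("xlsx")
  writeCompareTable(tab, pc)
  writeCompareTable(tab, px, style = styleSpec())
  gc <- readCompareGrid(pc)
  gx <- readCompareGrid(px)
  expect_identical(dim(gc), c(5L, 3L))
  expect_identical(gc, gx)
  expect_identical(gc, referenceCompareGrid())
  # empty table: header-only file
  empty <- compareSections(buildSubjectDocument("enriched"), "Date",
                           "None_*")
  pe <- tmpPath("csv")
  writeCompareTable(empty, pe)
  expect_identical(nrow(readCompareGrid(pe)), 2L)
})
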