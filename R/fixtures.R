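# In-package corpus: the daily animal score-sheet example used throughout
# the documentation, and a seeded random-document generator for property
# testing. No external data is required.

#' Build the template score sheet
#'
#' A minimal daily animal score sheet: one score section under
#' \code{/Subject} holding the measures recorded each measurement day —
#' \code{Date} (date), \code{Weight} (float, unit \code{g}),
#' \code{Experimenter} (string) and \code{Comment} (text). Date, Weight
#' and Comment start with empty value lists; Experimenter is pre-filled
#' with the default \code{"Alice"} (the person most likely to take the
#' measurement), so templates written from this document carry that
#' default.
#'
#' @return An \linkS4class{odmlDocument} that passes
#'   \code{\link{validateDocument}}.
#' @export
buildScoresheetTemplate <- function() {
  odmlDocument(sections = list(
    odmlSection("Subject", type = "subject", sections = list(
      odmlSection("Scores_YYYY-MM-DD", type = "scores", properties = list(
        odmlProperty("Date", dtype = "date"),
        odmlProperty("Weight", dtype = "float", unit = "g"),
        odmlProperty("Experimenter", values = list("Alice"),
                     dtype = "string"),
        odmlProperty("Comment", dtype = "text")
      ))
    ))
  ))
}

.scoreSection <- function(day, date, weight, experimenter, comment) {
  odmlSection(paste0("Scores_", day), type = "scores", properties = list(
    odmlProperty("Date", values = list(as.Date(date)), dtype = "date"),
    odmlProperty("Weight", values = list(weight), dtype = "float",
                 unit = "g"),
    odmlProperty("Experimenter", values = list(experimenter),
                 dtype = "string"),
    odmlProperty("Comment",
                 values = if (is.null(comment)) list() else list(comment),
                 dtype = "text")
  ))
}

#' Build the two-day subject document
#'
#' The merged metadata collection of two recording days:
#' \code{/Subject/Scores_2000-01-01} (Date 2000-01-01, Weight 5.0 g,
#' Experimenter Alice) and \code{/Subject/Scores_2000-01-02} (Date
#' 2000-01-02, Weight 5.5 g, Experimenter Bob). At stage
#' \code{"pre_enrichment"} both \code{Comment} properties are empty — the
#' document's only two empty-valued properties, the ones the empty-value
#' filter surfaces. At stage \code{"enriched"} they carry the manually
#' entered notes: day 1 \code{"Blood sample was taken [...]"}, day 2
#' \code{"Small scratch at the right ear"}.
#'
#' Day-1 Experimenter is the single value \code{"Alice"}; overview
#' renderings with genuinely multi-valued properties are exercised
#' separately in the tests.
#'
#' @param stage \code{"pre_enrichment"} or \code{"enriched"}.
#' @return An \linkS4class{odmlDocument}.
#' @export
buildSubjectDocument <- function(stage = c("pre_enrichment", "enriched")) {
  stage <- match.arg(stage)
  enriched <- identical(stage, "enriched")
  odmlDocument(sections = list(
    odmlSection("Subject", type = "subject", sections = list(
      .scoreSection("2000-01-01", "2000-01-01", 5.0, "Alice",
                    if (enriched) "Blood sample was taken [...]" else NULL),
      .scoreSection("2000-01-02", "2000-01-02", 5.5, "Bob",
                    if (enriched) "Small scratch at the right ear" else NULL)
    ))
  ))
}

#' The reference overview table of the enriched subject document
#'
#' The expected \code{\link{compareSections}} output for properties
#' Date/Weight/Experimenter/Comment over the \code{Scores_*} sections of
#' \code{buildSubjectDocument("enriched")}: Weight cells carry the unit
#' directly appended (\code{"5.0g"}, \code{"5.5g"}).
#'
#' @return Character matrix (including the label row and column).
#' @export
referenceCompareGrid <- function() {
  rbind(
    c("", "Scores_2000-01-01", "Scores_2000-01-02"),
    c("Date", "2000-01-01", "2000-01-02"),
    c("Weight", "5.0g", "5.5g"),
    c("Experimenter", "Alice", "Bob"),
    c("Comment", "Blood sample was taken [...]",
      "Small scratch at the right ear")
  )
}

.rndName <- function(prefix, i) paste0(prefix, "_", i)

.rndWord <- function(lenRange = c(3, 8)) {
  n <- sample(lenRange[1]:lenRange[2], 1)
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

.rndValue <- function(dtype) {
  switch(dtype,
    int = sample.int(2000L, 1) - 1000L,
    float = round(stats::runif(1, -100, 100), 3),
    string = .rndWord(),
    text = paste(.rndWord(), .rndWord()),
    url = paste0("http://example.org/", .rndWord()),
    person = paste(.rndWord(c(3, 6)), .rndWord(c(3, 8))),
    boolean = sample(c(TRUE, FALSE), 1),
    date = as.Date("2000-01-01") + sample.int(3650L, 1),
    time = sprintf("%02d:%02d:%02d", sample.int(24L, 1) - 1L,
                   sample.int(60L, 1) - 1L, sample.int(60L, 1) - 1L),
    datetime = sprintf("%sT%02d:%02d:%02d",
                       format(as.Date("2000-01-01") + sample.int(3650L, 1),
                              "%Y-%m-%d"),
                       sample.int(24L, 1) - 1L, sample.int(60L, 1) - 1L,
                       sample.int(60L, 1) - 1L)
  )
}

#' Generate a seeded random document
#'
#' Reproducible generator for property-style tests: the result is a pure
#' function of the parameters (the caller's RNG state is saved and
#' restored; generation uses R's Mersenne-Twister stream seeded with
#' \code{seed}, which is stable across platforms). Generated documents
#' always validate and, with the default ranges, cover nested sections,
#' multi-value and empty-value properties and all requested data types.
#'
#' @param seed Integer seed.
#' @param maxDepth Maximum section nesting depth (>= 1).
#' @param branching Maximum number of subsections per section.
#' @param propertiesPerSection Length-2 inclusive range of properties per
#'   section; the default minimum of 1 keeps every section visible to the
#'   tabular dialect (sections without properties anywhere below them have
#'   no tabular representation).
#' @param valuesPerProperty Length-2 inclusive range of values per
#'   property; 0 produces empty-valued properties.
#' @param dtypes Pool of canonical data types to draw from.
#' @param tabularSafe When \code{TRUE} (default) the generator emits only
#'   attributes the tabular dialect carries; when \code{FALSE} sections may
#'   additionally carry \code{link}/\code{include}/\code{repository}
#'   (preserved by hierarchical formats only).
#' @return An \linkS4class{odmlDocument}.
#' @examples
#' d1 <- randomDocument(1)
#' d2 <- randomDocument(1)
#' odmlEquals(d1, d2, ignoreIds = TRUE)  # TRUE
#' @export
randomDocument <- function(seed, maxDepth = 3, branching = 2,
                           propertiesPerSection = c(1, 3),
                           valuesPerProperty = c(0, 3),
                           dtypes = c("int", "float", "string", "text",
                                      "boolean", "date", "time", "datetime",
                                      "url", "person"),
                           tabularSafe = TRUE) {
  stopifnot(maxDepth >= 1, branching >= 0,
            all(propertiesPerSection >= 0), all(valuesPerProperty >= 0))
  withSeed(seed, {
    counter <- 0L
    makeProperty <- function(i) {
      dt <- sample(dtypes, 1)
      nv <- sample(valuesPerProperty[1]:valuesPerProperty[2], 1)
      vals <- lapply(seq_len(nv), function(k) .rndValue(dt))
      odmlProperty(
        name = .rndName("prop", i),
        values = vals,
        dtype = dt,
        definition = if (stats::runif(1) < 0.3) .rndWord() else NULL,
        unit = if (dt %in% c("int", "float") && stats::runif(1) < 0.5) {
          sample(c("g", "mm", "ms", "uV"), 1)
        } else NULL,
        uncertainty = if (dt == "float" && stats::runif(1) < 0.3) {
          round(stats::runif(1, 0, 5), 2)
        } else NULL,
        valueOrigin = if (stats::runif(1) < 0.2) .rndWord() else NULL,
        reference = if (stats::runif(1) < 0.2) .rndWord() else NULL
      )
    }
    makeSection <- function(depth) {
      counter <<- counter + 1L
      np <- sample(propertiesPerSection[1]:propertiesPerSection[2], 1)
      props <- lapply(seq_len(np), makeProperty)
      nsub <- if (depth < maxDepth && branching > 0) {
        sample(0:branching, 1)
      } else 0L
      subs <- lapply(seq_len(nsub), function(k) makeSection(depth + 1))
      odmlSection(
        name = .rndName("sec", counter),
        type = sample(c("recording", "subject", "hardware", "analysis"), 1),
        definition = if (stats::runif(1) < 0.3) .rndWord() else NULL,
        reference = if (stats::runif(1) < 0.2) .rndWord() else NULL,
        link = if (!tabularSafe && stats::runif(1) < 0.2) {
          paste0("/", .rndWord())
        } else NULL,
        include = if (!tabularSafe && stats::runif(1) < 0.1) {
          paste0(.rndWord(), ".odml")
        } else NULL,
        repository = if (!tabularSafe && stats::runif(1) < 0.1) {
          paste0("http://terms.example.org/", .rndWord())
        } else NULL,
        properties = props,
        sections = subs
      )
    }
    ntop <- max(1L, sample(0:max(branching, 1L), 1))
    odmlDocument(
      author = if (stats::runif(1) < 0.7) .rndWord() else NULL,
      date = if (stats::runif(1) < 0.5) {
        format(as.Date("2000-01-01") + sample.int(3650L, 1), "%Y-%m-%d")
      } else NULL,
      version = if (stats::runif(1) < 0.3) "1.0" else NULL,
      repository = if (stats::runif(1) < 0.2) {
        paste0("http://repo.example.org/", .rndWord())
      } else NULL,
      sections = lapply(seq_len(ntop), function(k) makeSection(1))
    )
  })
}
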