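# odmlr

Hierarchical experiment metadata (odML 1.4) and flat score-sheet tables,
with lossless conversion between them.

Neurophysiology experiments (and repetitive acquisition workflows in
general) produce metadata that must end up in a standardized,
machine-readable hierarchy — but is collected day by day, by hand, in
spreadsheets. `odmlr` bridges the two: it implements the odML data model
(a `Document` containing typed `Section`s, which hold `Property`
key-value-list pairs with shared dtype/unit/uncertainty), reads and writes
it as XML, JSON and YAML, and converts it to and from a flat tabular
dialect (csv/xlsx) in which each value occupies one row and the section
hierarchy is encoded in a `/`-joined *Path to Section* column. On top of
the conversion it provides the operations a metadata collection needs over
its lifetime:

- **templates** that fix the structure of future daily records,
- **merge** of a day's sheet into the growing collection (appending
  values, or overwriting them when enriching),
- **filter** pipelines over properties — e.g. extract every property with
  no values to see what is still missing,
- **compare** tables: printable overviews of selected properties across
  recording days,
- cell **highlighting** in xlsx output (defaults, missing values in red),
  ignored on reading back,
- a **CLI** (`inst/cli/odmlr`) exposing all five operations with
  persistable configurations.

The package is aimed at labs maintaining score sheets or device metadata,
and at analysts who receive odML files and want a spreadsheet view of
them.

## Worked example

The built-in corpus models a two-day animal score sheet. Build the
collection, pull out the unfilled entries, and render the overview table:

```r
library(odmlr)

doc <- buildSubjectDocument("enriched")
doc
#> odmlDocument: 3 sections, 8 properties, 8 values
#>   + Subject [subject] (0 properties)
#>     + Scores_2000-01-01 [scores] (4 properties)
#>     + Scores_2000-01-02 [scores] (4 properties)

compareSections(doc, c("Date", "Weight", "Experimenter", "Comment"),
                sectionSelector = "Scores_*")
#>               Scores_2000-01-01             Scores_2000-01-02
#> Date          2000-01-01                    2000-01-02
#> Weight        5.0g                          5.5g
#> Experimenter  Alice                         Bob
#> Comment       Blood sample was taken [...]  Small scratch at the right ear
```

Each cell is the property's value list with the unit appended directly
(`5.0g`); the table is presentation-only and can be written to csv/xlsx
with `writeCompareTable()` for the lab notebook.

The daily loop: write a template once, fill a copy each day, convert and
merge it into the master file:

```r
createTemplate("scores.xlsx", skeleton = buildScoresheetTemplate())
# ... the experimenter fills the sheet in a spreadsheet program ...
day <- readOdmlXlsx("scores.xlsx")
master <- mergeDocuments(master, day)          # appends the new section

# which entries are still empty?
empty <- filterDocument(master, filterSpec(filterStep("keep",
  list(comparison("value_count", "equals", 0)))))
documentCounts(empty)
#>   sections properties     values
#>          3          2          0

# after editing the filtered sheet, merge it back, replacing values:
master <- mergeDocuments(master, edited, overwriteValues = TRUE)
```

All five file formats round-trip: hierarchical formats exactly (including
UUIDs), tabular formats up to the dialect's declared losses (fresh UUIDs,
attributes of property-less sections, section `link`/`include`/
`repository`). `validateDocument()` reports every model violation with
the path of the offending entity.

From a shell:

```sh
odmlr convert scores.xlsx scores.odml --layout layout.cfg
odmlr merge master.odml scores.odml master.odml
odmlr filter master.odml todo.csv --empty-values
odmlr compare master.odml overview.csv --properties Date,Weight,Comment --sections 'Scores_*'
```

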