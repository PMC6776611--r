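---
title: "Hierarchical metadata, flat tables: the odmlr data model and dialect"
author: "odmlr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical metadata, flat tables: the odmlr data model and dialect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odmlr)
```

## The problem

Experimental laboratories accumulate metadata — animal health measures,
device settings, session notes — in repetitive acquisition cycles, and the
people entering them are rarely the people who later query them. The odML
format (open metadata Markup Language) stores such metadata as a
machine-readable hierarchy, but hierarchies are awkward to fill in by hand
during a daily routine. The practical middle ground is a flat spreadsheet
whose structure is rigid enough to be converted back into the hierarchy
without loss. `odmlr` implements both representations, the conversion
between them, and the operations a metadata collection needs over its
lifetime: template generation, day-by-day merging, filtering for unfilled
entries, and printable overview tables.

## The entity model

An `odmlDocument` holds file-level attributes (author, date, version,
repository) and a tree of `odmlSection` nodes. Sections carry a name and a
type and group `odmlProperty` leaves: extended key-value pairs holding an
ordered *list* of values that share one data type, unit and uncertainty.
Sharing those attributes across the value list is a deliberate modelling
constraint (one weight series cannot silently mix grams and kilograms);
`validateDocument()` reports any violation, along with duplicate sibling
section names, duplicate property names within a section, malformed UUIDs
and negative uncertainties. Every entity carries a version-4 UUID so that
the same property can be recognized across files; UUIDs are minted at
construction when not supplied.

Legacy files in the older model, where each value is its own XML entity
carrying its own dtype/unit/uncertainty, are upgraded on read: the value
entities collapse into the property's value list. When the value-level
attributes of one property disagree, the default (`strict`) mode refuses
with an error naming the property, because guessing would corrupt units.
The optional `lenient` mode splits the property into suffixed properties
(`name_1`, `name_2`, ...), one per attribute combination, conserving the
total number of values. Attributes outside the documented legacy model are
not interpreted.

## Serialization formats

XML is the canonical format: the root element carries `version="1.4"`,
which is required on write and checked on read. JSON and YAML renderings
mirror the XML element tree one-to-one, with one deliberate choice: values
are stored as their dialect-formatted *strings* rather than native
JSON/YAML scalars. This keeps a single coercion path for all five formats
and sidesteps YAML's implicit typing (`True`, `5.5` and dates would
otherwise change type in transit); on read, YAML scalar conversion is
suppressed for the same reason. All files are UTF-8.

## The data-type registry

The registry fixes ten canonical types (`int`, `float`, `string`, `text`,
`boolean`, `date`, `time`, `datetime`, `url`, `person`), their synonyms
(`integer`, `bool`, `str`, ...), and a default value per type, used when a
table cell is empty and for highlighting. The default table is a design
choice of this package — unambiguous, sortable sentinels: `0`, `0.0`,
empty text, `False`, `1900-01-01`, `00:00:00`, `1900-01-01T00:00:00` — and
is user-overridable through `dtypeRegistry()`. Dates and times are ISO
8601, which is locale-free. Boolean cells accept
`True`/`true`/`1`/`False`/`false`/`0`, because spreadsheet exports vary.
Floats always render with a decimal point (`5` becomes `"5.0"`), so a
weight prints as the familiar `5.0g` in overview tables; when R's default
15-significant-digit rendering would not re-parse to the identical double,
the formatter falls back to 17 digits, making `coerceValue(formatValue(v))`
the identity for every finite value.

## The flat dialect

`flattenDocument()` emits exactly one row per value, in depth-first
document order (a section's properties before its subsections). The
section hierarchy is encoded in a `"/"`-joined path column whose last
component is the section name; section names therefore may not contain
`"/"`, enforced at construction. A property with no values still yields
one row, with an empty value cell. Document attributes do not fit the row
model and occupy a separate top row
(`"Document Information", "author", <author>, "date", <date>, ...`), with
fixed positions so the row is machine-parseable without a second header.

Two empties must not collide: an empty cell means *no value* (a missing
entry to be filled in later), while a value that *is* the empty string is
written as a literal quote pair `""`. Without the sentinel the two would
be indistinguishable after a spreadsheet round trip.

Compaction improves readability: a cell identical to the cell above is
blanked, per column group — the section-level columns blank while the path
is unchanged, the property-level columns additionally require an unchanged
property name, and a section change resets everything below it. Value
cells are never blanked. `expandRows()` inverts this by forward-filling
under the same reset rule, so intentionally absent attributes of a *new*
property are never polluted by the property above.

Three losses are inherent to the dialect and declared rather than worked
around: entity UUIDs have no column (table round trips mint fresh ones);
sections that own no properties anywhere below them produce no rows at
all, and a section that has descendants but no properties of its own
survives only as a path component, losing its type/definition; and the
section attributes `link`, `include` and `repository` (plus section-level
`reference`) have no column. `odmlEquals(..., ignoreLossy = TRUE)`
implements exactly this equivalence, which is what the tabular round-trip
tests assert; hierarchical round trips are exact, including UUIDs.

## Tables on disk

csv output is RFC 4180 (comma, double-quote quoting, LF, UTF-8). xlsx
output is a single worksheet with the same logical grid; since no
installed R package writes xlsx, the package includes a small
SpreadsheetML writer (inline strings, solid-fill styles) and a reader that
also understands shared strings, so workbooks edited in Excel or
LibreOffice load back. The test suite cross-checks the writer against an
independent xlsx reader and the reader against a workbook produced by an
independent writer.

Columns are matched to odML attributes *by header name*, so users may
reorder or drop optional columns; custom display headers are allowed as
long as the same header map is supplied when reading back — a file written
with `Measure` for `Property Name` cannot be interpreted without that
mapping, and the reader says so. Styling is presentation only: alternating
section/property block fills, a highlight for value cells equal to their
type's registry default, and red (`FF0000` by default) for missing values.
Reading ignores all coloring, which is fuzz-tested with random palettes.

## Operations

**Merge** walks both trees by section name. Entities present only in the
source are appended with their UUIDs; entities present in both are merged
with the target's UUID kept. For a property in both documents the source
values are *appended* by default — which requires dtype, unit and
uncertainty to agree, otherwise the merge errors — or *replace* the
target's when `overwriteValues = TRUE`. Scalar attribute conflicts resolve
to the target in append mode and to the source in overwrite mode,
symmetric with the value semantics. The laws the tests hold the
implementation to: merging with an empty document is the identity,
overwrite self-merge is idempotent, and append-mode merge conserves the
multiset of (property path, value) pairs.

**Filter** operates at property granularity. A step keeps or rejects
properties by comparisons over `path`, `section_name`, `section_type`,
`property_name`, `value`, `data_unit`, `odml_data_type` or `value_count`
(`equals` / `contains` / `matches` / `is_empty`, combined with `all` or
`any`), or by a custom predicate. Steps compose left to right: each step
filters the survivors of the previous one, so `keep` intersects and
`reject` subtracts. A comparison on `value` holds when *any* value of the
property satisfies it. Ancestor sections survive only as housing for kept
properties (attributes copied verbatim); whether to keep empty ancestors
was genuinely open, and pruning was chosen because the flagship use —
extracting all properties with no values — should produce the smallest
editable sheet.

**Compare** produces a presentation-only grid: one column per section
matched by a glob on section names, one row per requested property. Cells
render the value list with the unit appended directly to each value with
no space (`5.0g`), values joined by `", "`. Appending the unit per value
rather than once per cell is this package's choice; the single-value cells
of typical score sheets render identically either way. The grid is not a
valid flat table and intentionally has no reverse conversion.

**Template** writes a table whose rows fix the structure of future
records. Values present in the skeleton (a default experimenter, a fixed
unit) are kept as pre-filled defaults; everything else stays empty.

## The generator and what the tests show

`randomDocument(seed, ...)` is a pure function of its parameters: it runs
R's Mersenne-Twister stream under the given seed (restoring the caller's
RNG state) and mints UUIDs from the same stream, so identical parameters
give identical documents on every platform. It emulates the features the
dialect must survive: nesting to `maxDepth`, sibling sections, value lists
of length 0–3 (empty-valued properties included), all ten data types,
optional units/uncertainties/definitions/provenance fields, and —
outside `tabularSafe` mode — the hierarchical-only attributes. Defaults
(depth 3, branching 2, 1–3 properties per section) give documents of
roughly 5–40 properties, the scale of a hand-maintained score-sheet
collection.

It does not emulate real-world collections of thousands of values,
cross-file `include` resolution, malformed third-party spreadsheets, or
adversarial text (cells containing unbalanced quote pairs of the sentinel
form). Passing the property suites therefore demonstrates the algebraic
correctness of the dialect and operations, not performance at archive
scale or robustness to arbitrary foreign files.

Problem sizes in the shipped suites — 200 seeded documents for the
round-trip and inverse-pair properties, 100 for the filter-versus-brute-
force oracle, 50 for merge laws, 10 random palettes for the styling fuzz —
were chosen to exercise every generator feature many times over while
keeping the default test run comfortably interactive.

## Known limitations

- `link`/`include` are stored and round-tripped verbatim, never
  dereferenced.
- Only single-worksheet workbooks in the dialect are supported; arbitrary
  third-party spreadsheets are out of scope.
- Numeric xlsx cells written by other tools are read as their stored
  lexical form; date-serial cells are not decoded (the dialect stores ISO
  text).
- User-defined validation rules embedded in odML files are not supported;
  `validateDocument()` checks the model invariants only.
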