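Package: odmlr
Title: Hierarchical odML Metadata and Tabular Score-Sheet Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for managing scientific experiment metadata in the
    hierarchical odML 1.4 format (open metadata Markup Language) and a flat
    tabular dialect suited to spreadsheet-based laboratory routines such as
    daily animal score sheets. Reads and writes odML documents as XML
    (canonical), JSON and YAML, transparently upgrading legacy v1.3 files;
    converts documents to and from csv and xlsx tables in which every value
    occupies one row and the section hierarchy is encoded as a "/"-delimited
    path column, with optional compaction of repeated cells, customizable
    column headers and cell highlighting of default or missing values.
    Provides template generation, merging of collections with optional value
    overwriting, multi-step property filtering, and presentation-only
    comparison tables across sections, plus a command-line interface
    exposing the same operations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml,
    zip
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
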