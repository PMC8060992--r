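Package: metnav
Title: Interactive Exploration of Metabolic Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Build, read and write metabolic reaction networks (SBML Level 3
    core and a lossless annotated JSON format), compute per-metabolite
    precursor and successor neighborhoods with currency-metabolite
    filtering and reversibility-aware direction semantics, interactively
    construct a single linear metabolic path with extension, replacement,
    reaction selection and a restorable path history, share paths as
    URL-safe link strings, and render vertical linear pathway diagrams in
    plain text and SVG. Includes a seeded synthetic-network generator and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    xml2,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
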