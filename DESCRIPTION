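Package: sonq
Title: Spreadsheet-Specified Search Ontologies and an Extended Boolean Query Engine
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compiles domain-specific search ontologies (dSONs) from a
    spreadsheet template into OWL and JSON documents whose concepts carry
    generated search-query strings in an extended Lucene-style syntax, and
    provides a reference query engine that executes those queries (boolean
    operators, MODE term types, NEAR proximity including sentence and
    paragraph scope, boost and wildcard) over tokenized plain-text document
    collections. Designed for ontology-driven literature screening such as
    post-market surveillance of medical devices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    readxl,
    xml2,
    jsonlite,
    stringi,
    zip,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
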