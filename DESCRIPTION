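Package: taxrecon
Title: Taxonomic Name Reconciliation Against a Local NCBI Taxonomy
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconciles arbitrary biological name strings against a locally
    stored copy of the NCBI taxonomy. Provides strict, case-insensitive, and
    fuzzy (edit-distance) name matching with explicit, typed ambiguity
    signalling suitable for unattended pipelines; division- and
    subtree-restricted search pools; synonym, vernacular, and homonym
    resolution; lineage navigation (parent, children, descendants, lowest
    common ancestor); and taxonomy-based distance matrices with configurable
    rank scores. Includes a taxdump fixture generator so the whole toolkit is
    testable offline, a portable columnar cache, and a command-line interface
    for batch reconciliation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14),
    stringi,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
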