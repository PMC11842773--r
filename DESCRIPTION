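Package: qudtmapper
Title: Map Ad Hoc Unit Strings to the QUDT Units Ontology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harmonizing the uncontrolled, ad hoc unit strings found
    in ecological and environmental metadata. Raw unit descriptions are
    normalized to canonical lowercase "pseudounits" and then rewritten into
    QUDT unit codes by two ordered sets of literal string substitutions. The
    resulting matches are assembled into an enriched lookup table keyed by raw
    unit, pseudounit, QUDT code, or UCUM alias, which supports value
    conversion between dimensionally compatible units, corpus-level match
    statistics, a lookup service, and the insertion of machine-readable
    annotation elements into EML 2.2 metadata documents.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
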