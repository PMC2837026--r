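Package: biolitmark
Title: Inline Semantic Markup of Biomedical Text with Ontology Terms and
    Database Identifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recognizes ontology terms (preferred names and synonyms from
    locally supplied OBO-format ontologies) and biological database
    identifiers (PDB, UniProtKB, GenBank, RefSeq accessions, matched by
    regular expression) in plain text or JATS-like XML fragments, and
    embeds the results as inline NLM/JATS mark-up: named-content elements
    with content-type "biolit" for ontology terms and ext-link elements
    for database identifiers.  Annotations are non-overlapping,
    longest-match spans; ambiguous spans carry all candidate terms and are
    resolved by a decisions file, an auto-single rule, or programmatic
    choice.  Includes ontology search and hierarchy navigation, a
    round-trippable mark-up parser that preserves foreign XML, a
    declarative run configuration, and a seeded fixture generator that
    produces toy ontologies and documents with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
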