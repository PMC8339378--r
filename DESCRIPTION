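Package: psychonto
Title: Ontology-Based Categorization of Psychological State and Trait Markers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for ontology-based modelling of human character,
    behavior and situation. Ships a psychologically driven concept schema
    (T-Box), relation inventory and constraint set covering affective
    processes, personality traits, health behaviors and learning; person
    profiles (A-Box) built from survey exports and free-text feeling
    reports via a lexicon and instrument codebooks; a forward-chaining
    rule engine with an if-then (A -> C) rule language and built-in rule
    presets for sleep hygiene, personality-sleep associations and
    behavioral-inhibition completion; behavior-stream semantics
    (singular versus habitual classification and cross-wave behavior
    change detection); knowledge-base consistency checking and
    hypothesis testing against profile collections; Turtle
    serialization; and a seeded synthetic cohort generator emulating the
    instrument battery for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
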