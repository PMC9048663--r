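Package: pathcurator
Title: Pathway-Centric Curation of Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extending genome-scale metabolic models one pathway at
    a time. Reads and writes constraint-based models in COBRA JSON, parses
    pathway records in KEGG flat-file, BioCyc ptools-xml and BiGG JSON
    dialects from a local cache, and converts them into model objects. Newly
    added metabolites, reactions and pathways pass through a curation battery
    (duplicates, missing chemical formulas, elemental and charge balance,
    reversibility consistency) that warns rather than aborts and writes a
    complete log. A non-zero flux test probes each reaction's capability to
    carry steady-state flux, inserting auxiliary boundary reactions at
    dead-end metabolites and translating every insertion into a manual
    curation suggestion. Pathways are laid out automatically as
    Escher-compatible map documents with optional flux-to-color overlays
    (linear or quantile normalized gradients).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
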