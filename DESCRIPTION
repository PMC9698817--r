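Package: odorspace
Title: Ontology-Based Mapping from Odorant Descriptors to Odor Perception Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a three-layer ontology of the odor perceptual space linking
    odor descriptors (OD) of single odorants, the odor qualities (OQ) flavorists
    reason with, and the odor sensory attributes (OSA) used by sensory panels.
    Free-text odorant descriptions from reference databases are tokenized into
    descriptor sets with citation-count intensities; expert elicitations and
    check-all-that-apply (CATA) questionnaires are fused into binary OD-to-OQ
    and OQ-to-OSA mappings; intensities are propagated linearly through the
    mappings to predict OQ and OSA profiles of odorants and of multi-odorant
    products such as wines. The ontology is serialized to and read from OWL 2
    (Turtle and RDF/XML) and supports the four class-level query patterns.
    Includes a synthetic-corpus generator with exact ground truth and
    proportion-based comparison of product profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
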