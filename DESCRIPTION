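Package: cynteract
Title: Cytonuclear Interaction Cataloguing from Structures, Targeting
    Databases and Curated Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a queryable catalog of direct cytonuclear molecular
    interactions for a plant nuclear proteome. Detects inter-chain contact
    residues in macromolecular structures of chimeric organellar complexes
    using a van der Waals overlap criterion, transfers contact sites to a
    target proteome by deterministic pairwise alignment, integrates
    subcellular-localization predictions from multiple databases into a
    five-way organelle-targeting consensus with manual-curation and Gene
    Ontology overlays, and joins everything into tab-separated catalog
    tables with an 11-category / 27-subcategory interaction scheme.
    Includes seeded synthetic-data generators (toy complexes with planted
    interfaces, prediction tables, mutated proteomes) so the whole pipeline
    is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
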