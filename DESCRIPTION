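Package: enrichkit
Title: Versioned Species-Specific Gene Function Libraries and Exact
    Over-Representation Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds versioned, species-specific term-to-gene function
    libraries from standard annotation files (OBO ontologies, GAF and
    NCBI gene2go/gene_info annotation tables, and flat pathway or
    disease association tables), propagating Gene Ontology annotations
    over is_a and part_of relations, and performs over-representation
    analysis of user gene sets with exact one-sided tail tests
    (Fisher/hypergeometric), Benjamini-Hochberg and related
    multiple-testing corrections, user-defined background gene lists,
    and bar and bubble visualisations. Includes a deterministic
    synthetic-fixture generator for end-to-end testing and a
    pipeline-embeddable command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
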