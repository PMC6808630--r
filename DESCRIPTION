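Package: bioschemarkup
Title: Bioschemas Structured-Data Markup for Scholarly Articles and Their
    Semantic Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts JATS-encoded scholarly-article metadata (as returned by
    the PubMed Central open-access OAI-PMH interface) and PubAnnotation-format
    semantic annotations into schema.org/Bioschemas JSON-LD structured-data
    records. Ships the five draft Bioschemas literature profiles (journal,
    volume, issue, scholarly article, semantic annotation) as an editable
    tiered property table, validates markup documents against them, embeds
    markup into HTML pages, and generates sitemaps for article collections.
    Includes deterministic synthetic-fixture generators for both input
    formats so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
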