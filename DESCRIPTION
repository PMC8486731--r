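Package: taxograph
Title: Build Linked Open Data Knowledge Graphs from Taxonomic Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts taxonomic articles marked up in TaxPub or TaxonX XML and
    Darwin Core backbone-taxonomy tables into named-graph RDF (quads) under a
    biodiversity publishing data model. Provides a minimal RDF quad store built
    on tibbles with TriG and N-Quads serialization and graph isomorphism
    testing; content-addressed, idempotent identifier minting (sha256 over
    type:label keys); a schema-driven recursive extractor over XML; typed RDF
    constructors for articles, people, sections, scientific names, taxonomic
    name usages, materials, institutions and external identifiers; backbone
    import as taxonomic concepts with SKOS hierarchy and reified RCC-5
    relations; nomenclatural update rules (replacement and related names) and a
    name-validity decision procedure; and a catalogue of competency queries
    evaluated directly over the quad table. Ships a deterministic synthetic
    fixture generator for both XML dialects and backbone trees with closed-form
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    generics,
    stringi,
    readr,
    xml2,
    jsonlite,
    ggplot2,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
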