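# taxograph

Build Linked Open Data knowledge graphs from taxonomic literature.

Taxonomic journals publish their articles as structured XML — TaxPub (an
extension of the NLM/JATS journal DTD) for born-digital articles, TaxonX
for legacy treatments — in which scientific names, treatment sections,
specimen records and authors are marked up at publication time. taxograph
converts that markup, together with a Darwin Core backbone-taxonomy
table, into named-graph RDF under a biodiversity publishing data model
(SPAR ontologies, Darwin Core, FOAF, SKOS, and `openbiodiv:` domain
classes), then derives nomenclatural relations and answers competency
queries over the result, entirely in R.

The core ideas:

* **Reified name usages.** Every mention of a scientific name becomes an
  `openbiodiv:TaxonomicNameUsage` resource linked to the name it
  mentions (`pkm:mentions`), to the article part that contains it
  (`po:isContainedBy` / `po:contains`, both directions materialized) and
  to its nomenclatural status (`dwciri:taxonomicStatus`).
* **Content-addressed identifiers.** Resources are keyed by
  `sha256(type:label)`; a hit returns the stored IRI, a miss mints
  `http://openbiodiv.net/<UUID>`. Converting a document twice mints
  nothing the second time, and the same author or name in two articles
  resolves to one IRI.
* **Schema-driven recursive extraction.** A declarative JSON schema per
  dialect says which XML nodes to visit, which text fields (atoms) to
  pull out and which constructor builds the RDF; the engine is a single
  recursive divide-and-conquer procedure.
* **Backbone taxonomy as concepts.** Each backbone row yields a
  taxonomic concept (`…-4239`), its scientific name (`…-4239-scName`)
  and its concept label (`…-4239-label`, `"name sec. citation"`), with
  the hierarchy encoded both as `skos:broader` and as reified RCC-5
  proper-part statements.
* **Update rules and validity.** Replacement-name and related-name edges
  are derived by graph pattern matching into a dedicated Updates graph;
  a name is invalid iff it has been replaced (transitively, with no loop
  back) or made unavailable without a later revalidation.
* **A 12-query competency catalogue** (most prolific authors,
  most-mentioned names, figures of an article, taxonomic discoveries in
  a family, institutional impact, collectors of a genus, holotype ↔
  genomic-accession ↔ institution links, …) evaluated directly on the
  quad table; the equivalent SPARQL text ships in `inst/queries/`.

## Worked example

Generate a small synthetic TaxPub article (three authors, two
treatments, materials with a holotype and a GenBank accession, two
figures), convert it, run the update rules and ask questions:

```r
library(taxograph)

st  <- id_store(deterministic = TRUE)          # reproducible IRIs
fx  <- gen_taxpub(fixture_config(seed = 1))    # article + ground truth
doc <- parse_article(fx$xml, "taxpub", store = st, quiet = TRUE)

glance(doc)
#> # A tibble: 1 × 4
#>   n_quads n_graphs n_subjects n_typed
#>     <int>    <int>      <int>   <int>
#> 1     207        1         54      54

pp <- postprocess_graph(doc)                   # update rules
nrow(pp$related)                               # 4 related-name edges

run_query(doc, "collectors_of_genus",
          list(genus = strsplit(fx$truth$name_labels[1], " ")[[1]][1]))
#> # A tibble: 1 × 3
#>   label         recorder    eventDate
#>   <chr>         <chr>       <chr>
#> 1 Toveza lurepa Radu Tazara 1996-12-19

check_validity(pp$doc, fx$truth$name_labels[1])
#> # A tibble: 1 × 5
#>   name_label    valid replaced unavailable reasons
#>   <chr>         <lgl> <lgl>    <lgl>       <chr>
#> 1 Toveza lurepa TRUE  FALSE    FALSE       ""
```

The 207 quads are one named graph (the article IRI); 54 typed resources
cover the article, authors, sections, treatments, name usages,
occurrence/event/location records, the institution and the accession.
`write_trig(doc, "article.trig")` serializes the graph;
`read_trig()` parses it back to an identical quad set.

Importing a backbone and joining it to the literature graph:

```r
bb <- gen_backbone(20, max_depth = 4, seed = 1)
g  <- import_backbone(bb$tsv, "GBIF Secretariat (2019)",
                      base_uuid = "F1DD0CF0-217D-422B-BAA4-58901976D7B4")
# 20 concepts, 20 -scName names, 20 -label labels,
# 19 skos:broader edges, 19 reified RCC-5 statements
```

A thin command-line surface is installed with the package
(`system.file("cli", "taxograph.R", package = "taxograph")`) with
`convert`, `import-gbif`, `postprocess`, `validate-name`, `query` and
`gen-fixtures` subcommands.

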