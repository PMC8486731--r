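---
title: "Building literature knowledge graphs from taxonomic articles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building literature knowledge graphs from taxonomic articles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxograph)
library(dplyr)
```

## The problem

Modern taxonomic journals publish structured XML: every scientific name,
treatment section, specimen record and author is marked up at publication
time (TaxPub for journal articles, TaxonX for legacy treatments). That
markup supports a much richer representation than a document store: a
knowledge graph in which a *taxonomic name usage* — one mention of a name
at one position in one article — is a first-class resource, linked to the
name it mentions, the section that contains it and the nomenclatural act
it performs. Once articles and a backbone taxonomy live in one graph,
questions that are tedious to answer from PDFs become joins: who has
collected specimens of a genus, which collections underpin which species
descriptions, whether a name is still valid.

taxograph converts the two XML dialects and a Darwin Core backbone table
into named-graph RDF (quads), applies the nomenclatural update rules that
derive name-to-name relations, and answers a catalogue of competency
queries directly in R.

## The data model in brief

Every resource is typed with community vocabularies: documents and their
components with the SPAR ontologies (`fabio:JournalArticle`,
`doco:Figure`, `deo:Introduction`), people with FOAF, biodiversity
entities with Darwin Core (`dwc:Occurrence`, `dwc:Event`,
`dwc:Identification`) and the domain-specific classes
(`openbiodiv:ScientificName`, `openbiodiv:TaxonomicNameUsage`,
`openbiodiv:Treatment`, `openbiodiv:TaxonomicConcept`) in the
`http://openbiodiv.net/` namespace. An article is typed both
`fabio:JournalArticle` and `fabio:ResearchPaper`: the SPAR work/expression
dichotomy is real, but queries are phrased against either class, and a
full work/expression split would add resources no query here needs.

Three representational choices run through everything:

* **No blank nodes.** Every resource receives a minted HTTP IRI, so any
  statement can be referenced across documents.
* **Bidirectional containment.** Both `po:contains` and its inverse
  `po:isContainedBy` are materialized at construction time. A triple
  store would infer one from the other; materializing both keeps the
  graph self-contained and makes inverse-free evaluation possible on the
  plain quad table.
* **One named graph per article** (the graph IRI is the article IRI).
  Update-rule insertions go to a dedicated graph,
  `http://openbiodiv.net/Updates`, so derived statements never mingle
  with asserted ones. Backbone imports use the version resource as their
  graph, which is what lets a later backbone version be ingested without
  touching an earlier one.

## Identifiers: content-addressed minting

Identifier reuse is the linchpin of cross-article linking: the second
article by the same author must resolve to the same person IRI. The
identifier service hashes the pair `type:label` (sha256 over UTF-8 bytes
of, e.g., `person:Guanyang Zhang`) and keeps a digest → IRI map. A hit
returns the stored IRI; a miss mints `http://openbiodiv.net/<UUID>` and
persists the record (JSON-lines, one record per line). Labels are
normalized first — whitespace collapsed, Unicode NFC — but **case is
preserved**, because case is significant in nomenclature (*Zelus* the
genus vs "zelus" a misprint are different keys). A flag could fold case
for corpora where that is wrong, but the default errs on the side of not
conflating names. Beyond exact normalized-label identity there is no
author disambiguation: rule-based disambiguation of author names has a
poor track record in this domain and is explicitly out of scope.

Structural resources (sections, usages, figures, occurrence records) are
content-addressed too, keyed by the article identifier plus the node's
XML path. That makes conversion **idempotent**: converting the same
document twice against the same store mints exactly zero new identifiers,
which the test suite checks and the run report exposes (the minted/reused
split is also the number to watch when conversion is slow — identifier
lookups dominate conversion time).

UUIDs are random (v4) in production. In deterministic mode the UUID is
derived from the key digest, so a full pipeline run is byte-reproducible —
that is what the golden-file regression tests and the reproducibility
script rely on.

## The extractor

Conversion is a single recursive procedure over the XML tree. For each
node the engine (1) extracts the node's *atoms* — text fields reachable
by relative XPath 1.0 expressions, element text or attribute values; (2)
dispatches to the node's *constructor*, which mints the IRI and emits the
node's quads; (3) recurses into each declared child node type, passing
the chain of ancestor IRIs down (constructors link only to the immediate
parent; deeper relationships are recovered by closure at query time).

What to extract is not code but data: two shipped JSON schema files (one
per dialect) declare, per node type, its location, atoms, constructor
name and children. `validate_schema_spec()` enforces the format contract
(a JSON Schema document ships next to the files) including acyclicity of
child references and that every constructor resolves. The TaxPub node
inventory follows the published markup conventions; the TaxonX
materials/occurrence paths are **provisional defaults** — real TaxonX
corpora vary, and the schema file is meant to be edited.

One extraction step cannot be expressed as a single XPath: author
affiliations. The `xref` of an author carries an `rid` that published XML
matches against `aff` elements by three different conventions, sometimes
within one journal. The resolver tries, in order: exact `@id` match,
`@id` equal to `"A" + rid`, and label-text equality — the cascade exists
because printed XML really does mix `rid="3"` with `id="A3"`.

Regularized name parts take precedence over displayed text: a genus
displayed as the abbreviation "P." but regularized as "Zelus" yields the
label "Zelus casii". The rank is read from the most specific name part.
Unparseable dates are kept as plain literals with a warning rather than
dropped — a wrong-format date is still evidence.

## Nomenclatural statuses and update rules

The status printed in a nomenclature section ("sp. nov.",
"comb. nov.", "nomen dubium"…) maps to one of four status classes:
discovery, replacement name, unavailable name, available name. The
mapping is a shipped, editable CSV — statuses are editorial vocabulary,
not code — and unknown statuses simply produce no status triple.

Two rules run after a corpus is loaded (set semantics make both
idempotent):

* **Replacement name**: if a usage with replacement-name status mentions
  name A inside a nomenclature section whose citations list contains a
  usage of name B *of the same verbatim rank*, then
  `B openbiodiv:replacementName A`. The shared-rank condition is part of
  the join, so a species can never "replace" a genus.
* **Related name**: any two distinct names whose usages occur in the same
  nomenclature section are mutually related — a section with k distinct
  names yields k(k−1) directed edges. "In the section" is read as
  containment at any depth, because cited usages sit two levels below the
  section (citations list → citation → usage); a direct-child reading
  would make the rule vacuous for exactly the citations it is meant to
  relate.

**Name validity** is then a decision procedure: a name is invalid iff
(a) it has been replaced — there is an outgoing replacement chain and no
chain of replacement edges leads back to the name (a loop means the
community reversed itself, so "replaced" does not hold) — or (b) some
usage made it unavailable and no usage in a *strictly later* dated
article made it available again. Both a one-step approximation of (a)
(outgoing edge whose target has no further edge) and the full transitive
check are implemented; the verdict uses the transitive one, since the
no-loops wording is the actual criterion and the one-step form is only
its cheapest query approximation. Date comparison uses `xsd:date` value
order; usages in undated articles are excluded with a warning rather than
silently treated as older or newer.

## The backbone taxonomy

A backbone row (one taxonomic concept) becomes three resources sharing
the import run's base UUID with suffixed IRIs: the concept
(`…-<taxonID>`), its scientific name (`…-<taxonID>-scName`) and its
concept label (`…-<taxonID>-label`, with label text
`"<name> sec. <citation>"` — the `sec.` keyword fixes a name to a
circumscription source; the single-space separator is this package's
choice, the convention does not prescribe spacing). These are the only
suffixed IRIs in the system; everything else is a bare minted UUID.

The hierarchy is encoded twice, deliberately: `skos:broader` edges give
cheap transitive traversal, and a reified RCC-5 statement per
child–parent pair (relation: proper part) gives the extension point for
richer alignments — later backbone versions, or expert classifications
that overlap rather than nest, can add partial-overlap or disjointness
statements against the *same* names without touching existing concepts.
The reification property IRIs are configurable because the canonical
vocabulary file is maintained outside this package; the local names
follow the `ProperPart_INT` pattern.

Synonym rows contribute a name resource linked from their accepted
concept, but no concept and no hierarchy edge: the concept layer is the
accepted hierarchy, and synonymy is a name-level fact.

## The query catalogue

Twelve competency queries ship in two forms: SPARQL text
(`inst/queries/*.rq`, with `{{param}}` slots) for use against an external
SPARQL 1.1 endpoint, and native implementations evaluated directly on the
quad tibble with relational joins, which is what `run_query()` runs. The
native forms are the reference: where a printed query pattern assumes
containment shortcuts that the constructed graph does not assert
directly (an article "containing" a usage that actually sits three
levels down), the native implementation uses the containment closure,
and the 1-or-2-step pattern where the catalogue itself spells that form
out. Aggregates (counts, group-concatenation) follow the SELECT clauses.

## The synthetic corpus

The fixture generator is the package's test bed and demonstration
corpus. It emulates the structure conversion depends on: metadata with
DOI, publisher and ISO date; authors with ORCIDs and cross-referenced
affiliations (including the A-prefix id mismatch); treatments with
nomenclature sections, statuses, citation lists, materials-examined
sections carrying collector, event date, locality, type status, an
institution with a collection-registry identifier and a GenBank-style
accession; figures with name mentions; and, for TaxPub only, keyword
groups, an introduction and a reference list (TaxonX drops exactly the
structures the dialect does not mark up). Names are Latin-like binomials
built from syllable tables — real names carry real semantics, synthetic
ones cannot collide with them. Name placement follows fixed index
arithmetic, so the expected resource census, distinct-name set and
update-rule edges are computed **closed-form from the configuration**,
never by running the pipeline; the generator defaults (3 authors, 2
treatments, 6 names, 1 citation per nomenclature, one institution, one
accession, 2 figures) describe a small but complete taxonomic article.

What the generator does *not* emulate: realistic article length, prose,
OCR noise, inconsistent markup, publisher HTML, or names that defy the
genus–species shape (hybrids, cultivars). Passing tests therefore show
that the pipeline implements its contracts on well-formed markup; they do
not show robustness to the long tail of real-world markup damage.

Backbone fixtures are rank-consistent forests (ranks never invert along
a path, species sit under genera) with optional synonym rows.

## Numerical and procedural choices

* Quad equality is exact string equality after NFC normalization of
  literals; no datatype value-space coercion except `xsd:date` ordering
  in the validity check.
* Graph isomorphism (used to compare conversions against reference
  graphs whose instance UUIDs differ per run) renames only
  `http://openbiodiv.net/<UUID>` instance IRIs; vocabulary IRIs,
  suffixed backbone IRIs and literals must match verbatim. The search
  uses iterated color refinement to a partition fixpoint, then
  backtracking within color classes; an exhaustive-bijection oracle
  cross-checks it on small graphs in the test suite.
* The TriG parser covers the subset the package emits plus common
  hand-written forms (`@prefix`, predicate/object lists, language tags,
  typed literals, optional `GRAPH` keyword). Blank nodes are rejected by
  design — the data model mints IRIs for everything.
* Problem sizes in the shipped checks: 50 seeded fixtures per dialect
  for the extractor census, 100 for the update-rule/oracle comparison,
  20-taxon backbones, a three-article corpus for the query catalogue.
  These sizes exercise every join while keeping a full run comfortably
  interactive.

## Limitations

* No inference. Everything a reasoner would add must be materialized by
  the constructors (the inverse containment is; nothing else is). The
  package intentionally avoids subclass/subproperty expansion — in
  production deployments of this data model, ontology-wide inference
  multiplied statements 1.2–3.7× with little query benefit.
* `run_query()` is a catalogue, not a SPARQL engine: arbitrary SPARQL
  against the in-memory graph is out of scope (the `.rq` files exist for
  endpoints).
* Fuzzy label search is not provided; it requires an external search
  index.
* Author identity is exact-label identity; homonymous authors merge and
  name variants split.

## A worked run

```{r example}
st <- id_store(deterministic = TRUE)
fx <- gen_taxpub(fixture_config(seed = 1))
doc <- parse_article(fx$xml, "taxpub", store = st, quiet = TRUE)
glance(doc)

pp <- postprocess_graph(doc)
nrow(pp$related)

run_query(doc, "collectors_of_genus",
          list(genus = strsplit(fx$truth$name_labels[1], " ")[[1]][1]))

check_validity(pp$doc, fx$truth$name_labels[1])
```
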