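taxpub_schema <- load_schema("taxpub")
taxonx_schema <- load_schema("taxonx")
tp_ns <- c(tp = "http://www.plazi.org/taxpub")

test_that("author atoms are extracted from the reference markup", {
  ex <- worked_examples()[[2]]
  doc <- xml2::read_xml(ex$xml)
  node <- xml2::xml_find_first(doc, "//contrib[@contrib-type='author']")
  atoms <- extract_atoms(node, taxpub_schema$nodes$person,
                         taxograph:::schema_ns(taxpub_schema))
  expect_equal(atoms$surname, "Zhang")
  expect_equal(atoms$given_names, "Guanyang Zhang")
  expect_equal(atoms$orcid, "https://orcid.org/0000-0003-4389-4270")
  # optional atoms that do not resolve are absent, not null-valued
  expect_false("institution_name" %in% names(atoms))
})

test_that("taxon-name atoms prefer regularized part values", {
  ex <- worked_examples()[[1]]
  node <- xml2::read_xml(ex$xml)
  atoms <- extract_atoms(node, taxpub_schema$nodes$tnu, tp_ns)
  expect_equal(atoms$genus_reg, "Zelus")
  expect_equal(atoms$genus_verbatim, "P.")
  expect_equal(atoms$species_reg, "casii")
  expect_equal(atoms$rank, "species")
})

test_that("affiliation cross-references resolve through the id cascade", {
  ex <- worked_examples()[[2]]
  doc <- xml2::read_xml(ex$xml)
  node <- xml2::xml_find_first(doc, "//contrib")
  # printed rid '3' must match aff id 'A3' via the prefix rule
  expect_equal(
    resolve_affiliations(node, doc),
    paste0("Florida Museum of Natural History, University of Florida, ",
           "Gainesville, FL, USA"))

  # three-convention document: exact id, A-prefixed id, label text
  xml <- xml2::read_xml('<article><front><article-meta><contrib-group>
    <contrib contrib-type="author"><xref ref-type="aff" rid="one">1</xref></contrib>
    <contrib contrib-type="author"><xref ref-type="aff" rid="2">2</xref></contrib>
    <contrib contrib-type="author"><xref ref-type="aff" rid="3">3</xref></contrib>
    <contrib contrib-type="author"><xref ref-type="aff" rid="zzz">4</xref></contrib>
    </contrib-group>
    <aff id="one"><addr-line>First Place</addr-line></aff>
    <aff id="A2"><addr-line>Second Place</addr-line></aff>
    <aff id="other"><label>3</label><addr-line>Third Place</addr-line></aff>
    </article-meta></front></article>')
  contribs <- xml2::xml_find_all(xml, "//contrib")
  expect_equal(resolve_affiliations(contribs[[1]], xml), "First Place")
  expect_equal(resolve_affiliations(contribs[[2]], xml), "Second Place")
  expect_equal(resolve_affiliations(contribs[[3]], xml), "Third Place")
  expect_warning(out <- resolve_affiliations(contribs[[4]], xml),
                 "unresolvable")
  expect_length(out, 0L)
  # author with no xref
  no_xref <- xml2::read_xml("<contrib/>")
  expect_length(resolve_affiliations(no_xref, no_xref), 0L)

  # brute-force oracle: apply the three predicates over all affs directly
  affs <- xml2::xml_find_all(xml, "//aff")
  brute <- function(rid) {
    for (a in affs) {
      if (identical(xml2::xml_attr(a, "id"), rid)) return(a)
    }
    for (a in affs) {
      if (identical(xml2::xml_attr(a, "id"), paste0("A", rid))) return(a)
    }
    for (a in affs) {
      lab <- xml2::xml_find_first(a, "./label")
      if (!inherits(lab, "xml_missing") &&
          identical(xml2::xml_text(lab), rid)) return(a)
    }
    NULL
  }
  for (i in 1:3) {
    rid <- xml2::xml_attr(
      xml2::xml_find_first(contribs[[i]], "./xref"), "rid")
    expected <- xml2::xml_text(
      xml2::xml_find_first(brute(rid), "./addr-line"))
    expect_equal(resolve_affiliations(contribs[[i]], xml), expected)
  }
})

test_that("recursion produces per-type counts equal to independent XPath counts", {
  fx <- gen_taxpub(fixture_config(seed = 17))
  doc <- parse_article(fx$xml, taxpub_schema, id_store(), quiet = TRUE)
  xml <- xml2::read_xml(fx$xml)
  # independent oracle: count matches of the schema's locations directly
  n_treat <- length(xml2::xml_find_all(xml, "//tp:taxon-treatment", tp_ns))
  n_fig <- length(xml2::xml_find_all(xml, "/article/body/fig"))
  n_tnu <- length(xml2::xml_find_all(xml, "//tp:taxon-name", tp_ns))
  census <- type_census(doc)
  expect_equal(census[["openbiodiv:Treatment"]], n_treat)
  expect_equal(census[["doco:Figure"]], n_fig)
  expect_equal(census[["openbiodiv:TaxonomicNameUsage"]], n_tnu)
})

test_that("dialect coverage flags are honoured by the conversions", {
  cfg <- fixture_config(seed = 5)
  tp <- parse_article(gen_taxpub(cfg)$xml, taxpub_schema, id_store(),
                      quiet = TRUE)
  tx <- parse_article(gen_taxonx(cfg)$xml, taxonx_schema, id_store(),
                      quiet = TRUE)
  tp_census <- type_census(tp)
  tx_census <- type_census(tx)
  # present in TaxPub, absent from TaxonX
  for (cls in c("deo:Introduction", "openbiodiv:KeywordGroup",
                "doco:BibliographicReferenceList")) {
    expect_gte(tp_census[[cls]], 1L)
    expect_false(cls %in% names(tx_census))
  }
  # present in both
  for (cls in c("openbiodiv:Treatment", "sro:Abstract", "doco:Title",
                "orb:Discussion", "openbiodiv:MaterialsExamined",
                "deo:BibliographicReference", "doco:Figure")) {
    expect_gte(tp_census[[cls]], 1L)
    expect_gte(tx_census[[cls]], 1L)
  }
})

test_that("conversion is deterministic given a deterministic store", {
  fx <- gen_taxpub(fixture_config(seed = 9))
  t1 <- rdf_serialize(parse_article(fx$xml, taxpub_schema,
                                    id_store(deterministic = TRUE),
                                    quiet = TRUE), "trig")
  t2 <- rdf_serialize(parse_article(fx$xml, taxpub_schema,
                                    id_store(deterministic = TRUE),
                                    quiet = TRUE), "trig")
  expect_identical(t1, t2)
})

test_that("every converted resource connects to the article node", {
  fx <- gen_taxpub(fixture_config(seed = 21))
  doc <- parse_article(fx$xml, taxpub_schema, id_store(), quiet = TRUE)
  d <- tibble::as_tibble(doc)
  article <- oracle_typed(doc, "fabio:JournalArticle")
  expect_length(article, 1L)
  # undirected reachability over all IRI-object quads
  edges <- d[d$is_iri, c("subject", "object")]
  nodes <- unique(c(d$subject, d$object[d$is_iri]))
  reached <- article
  frontier <- article
  while (length(frontier) > 0L) {
    nxt <- unique(c(edges$object[edges$subject %in% frontier],
                    edges$subject[edges$object %in% frontier]))
    frontier <- setdiff(nxt, reached)
    reached <- c(reached, frontier)
  }
  expect_setequal(intersect(nodes, reached), nodes)
})

test_that("unknown roots and malformed schemas are rejected", {
  expect_error(parse_article("<foo/>", taxpub_schema, id_store()),
               "root")
  bad <- taxpub_schema
  bad$nodes$article$children <- c(bad$nodes$article$children, "ghost")
  expect_error(validate_schema_spec(bad), "ghost")
  bad2 <- taxpub_schema
  bad2$nodes$tnu$constructor <- "unknown_ctor"
  expect_error(validate_schema_spec(bad2), "unknown constructor")
  # both shipped schemas validate
  expect_true(validate_schema_spec(taxpub_schema))
  expect_true(validate_schema_spec(taxonx_schema))
})
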