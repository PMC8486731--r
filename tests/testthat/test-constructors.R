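frag <- "http://openbiodiv.net/Fragments"

test_that("article construction emits the printed metadata pattern", {
  st <- id_store(deterministic = TRUE)
  res <- make_article(list(doi = "10.3897/BDJ.4.e8150",
                           publisher = "Pensoft Publishers",
                           pub_date = "2016-07-08"), NULL, st)
  d <- tibble::as_tibble(res$doc)
  expect_true(any(d$predicate == expand_curie("prism:doi") &
                    d$object == "10.3897/BDJ.4.e8150"))
  # both publisher forms: the literal and the minted agent resource
  expect_true(any(d$predicate == expand_curie("dc:publisher") & !d$is_iri &
                    d$object == "Pensoft Publishers"))
  agent <- d$object[d$predicate == expand_curie("dcterms:publisher")]
  expect_length(agent, 1L)
  expect_true(is_instance_iri(agent))
  # date typed xsd:date
  date_row <- d[d$predicate == expand_curie("prism:publicationDate"), ]
  expect_equal(date_row$datatype, expand_curie("xsd:date"))
  # dual article typing so both query styles succeed
  types <- d$object[d$subject == res$iri &
                      d$predicate == expand_curie("rdf:type")]
  expect_true(all(expand_curie(c("fabio:JournalArticle",
                                 "fabio:ResearchPaper")) %in% types))
  expect_error(make_article(list(), NULL, st), "DOI")
  # missing date: no triple, no error
  res2 <- make_article(list(title = "T"), NULL, st)
  expect_false(expand_curie("prism:publicationDate") %in%
                 tibble::as_tibble(res2$doc)$predicate)
})

test_that("person construction handles ORCID, affiliations and agents", {
  st <- id_store(deterministic = TRUE)
  res <- make_person(list(surname = "Zhang",
                          given_names = "Guanyang Zhang",
                          orcid = "https://orcid.org/0000-0003-4389-4270",
                          affiliation = "Somewhere"),
                     list(graph_iri = frag), st)
  d <- tibble::as_tibble(res$doc)
  expect_true(any(d$predicate == expand_curie("datacite:hasIdentifier") &
                    d$object == "https://orcid.org/0000-0003-4389-4270"))
  expect_true(any(d$predicate == expand_curie("rdfs:label") &
                    d$object == "Guanyang Zhang"))
  # no ORCID, no identifier triple
  res2 <- make_person(list(surname = "Duco", given_names = "Ana"),
                      list(graph_iri = frag), st)
  expect_false(expand_curie("datacite:hasIdentifier") %in%
                 tibble::as_tibble(res2$doc)$predicate)
  # label assembled when given names do not already end with the surname
  d2 <- tibble::as_tibble(res2$doc)
  expect_true("Ana Duco" %in% d2$object)
  # institutional author becomes an agent
  res3 <- make_person(list(institution_name = "Consortium X"),
                      list(graph_iri = frag), st)
  d3 <- tibble::as_tibble(res3$doc)
  expect_true(expand_curie("foaf:Agent") %in% d3$object)
  expect_false(expand_curie("foaf:Person") %in% d3$object)
  # same normalized label in two contexts resolves to one IRI
  res4 <- make_person(list(surname = "Zhang",
                           given_names = "Guanyang  Zhang"),
                      list(graph_iri = frag), st)
  expect_identical(res4$iri, res$iri)
})

test_that("sections are typed per the data-type mapping with bidirectional containment", {
  st <- id_store(deterministic = TRUE)
  parent <- "http://openbiodiv.net/0BD7ED36-1192-47A5-99F9-113998EF3099"
  ctx <- list(graph_iri = frag, node_key = "k|/x/sec",
              parent_chain = list(list(iri = parent,
                                       resource_type = "article")))
  for (pair in list(c("introduction", "deo:Introduction"),
                    c("figure", "doco:Figure"),
                    c("citations_list",
                      "openbiodiv:NomenclatureCitationsList"),
                    c("treatment", "openbiodiv:Treatment"))) {
    ctx$node_key <- paste0("k|", pair[1])
    res <- make_section(list(), ctx, st, kind = pair[1])
    d <- tibble::as_tibble(res$doc)
    expect_true(any(d$object == expand_curie(pair[2]) &
                      d$predicate == expand_curie("rdf:type")))
    expect_true(any(d$subject == res$iri &
                      d$predicate == expand_curie("po:isContainedBy") &
                      d$object == parent))
    expect_true(any(d$subject == parent &
                      d$predicate == expand_curie("po:contains") &
                      d$object == res$iri))
  }
  expect_error(make_section(list(), ctx, st, kind = "nope"), "kind")
})

test_that("scientific names assemble labels from regularized parts", {
  st <- id_store(deterministic = TRUE)
  res <- make_scientific_name(
    list(genus_reg = "Zelus", genus_verbatim = "P.",
         species_reg = "casii", species_verbatim = "casii",
         rank = "species"),
    list(graph_iri = frag), st)
  d <- tibble::as_tibble(res$doc)
  expect_equal(res$label, "Zelus casii")
  expect_true(any(d$predicate == expand_curie("dwc:genus") &
                    d$object == "Zelus"))
  expect_true(any(d$predicate == expand_curie("dwc:verbatimTaxonRank") &
                    d$object == "species"))
  # uninomial family: label is the family, no epithet triple
  res2 <- make_scientific_name(list(family_reg = "Reduviidae"),
                               list(graph_iri = frag), st)
  d2 <- tibble::as_tibble(res2$doc)
  expect_equal(res2$label, "Reduviidae")
  expect_false(expand_curie("dwc:specificEpithet") %in% d2$predicate)
  expect_error(make_scientific_name(list(), list(graph_iri = frag), st))
  # same name twice: one IRI
  res3 <- make_scientific_name(
    list(genus_reg = "Zelus", species_reg = "casii"),
    list(graph_iri = frag), st)
  expect_identical(res3$iri, res$iri)
})

test_that("name usages mention exactly one name and carry mapped statuses", {
  st <- id_store(deterministic = TRUE)
  sm <- default_status_mapping()
  parent <- get_or_mint(st, "abstract", "k|abs")
  ctx <- list(graph_iri = frag, node_key = "k|/a/tnu1",
              status_mapping = sm,
              parent_chain = list(list(iri = parent,
                                       resource_type = "abstract")))
  res <- make_tnu(list(genus_reg = "Zelus", species_reg = "casii",
                       status = "sp. nov."), ctx, st)
  d <- tibble::as_tibble(res$doc)
  mentions <- d[d$subject == res$iri &
                  d$predicate == expand_curie("pkm:mentions"), ]
  expect_equal(nrow(mentions), 1L)
  expect_true(any(d$subject == res$iri &
                    d$predicate == expand_curie("dwciri:taxonomicStatus") &
                    d$object == expand_curie("openbiodiv:TaxonomicDiscovery")))
  # two usages of one name: two TNU IRIs, one name IRI
  ctx$node_key <- "k|/a/tnu2"
  res2 <- make_tnu(list(genus_reg = "Zelus", species_reg = "casii"),
                   ctx, st)
  expect_false(identical(res2$iri, res$iri))
  d2 <- tibble::as_tibble(res2$doc)
  expect_equal(d2$object[d2$predicate == expand_curie("pkm:mentions")],
               mentions$object)
  # unmapped status: no status triple
  ctx$node_key <- "k|/a/tnu3"
  res3 <- make_tnu(list(genus_reg = "Aus", species_reg = "bus",
                        status = "weird status"), ctx, st)
  expect_false(expand_curie("dwciri:taxonomicStatus") %in%
                 tibble::as_tibble(res3$doc)$predicate)
})

test_that("materials sections spawn occurrence, event, location and holotype records", {
  st <- id_store(deterministic = TRUE)
  treatment <- get_or_mint(st, "treatment", "k|t1")
  ctx <- list(graph_iri = frag, node_key = "k|/t/mat",
              parent_chain = list(list(iri = treatment,
                                       resource_type = "treatment")))
  res <- make_materials(list(recorded_by = "J. Smith",
                             event_date = "2003-05-01",
                             type_status = "holotype",
                             locality = "Mato Grosso",
                             identified_by = "A. Jones"), ctx, st)
  d <- tibble::as_tibble(res$doc)
  occ <- d$object[d$predicate == expand_curie("dwc:occurrenceID")]
  expect_length(occ, 1L)
  expect_true(any(d$subject == occ &
                    d$predicate == expand_curie("dwc:recordedBy") &
                    d$object == "J. Smith"))
  ev <- d$object[d$predicate == expand_curie("dwc:eventID")]
  expect_true(any(d$subject == ev &
                    d$predicate == expand_curie("dwc:eventDate") &
                    d$object == "2003-05-01"))
  loc <- d$object[d$predicate == expand_curie("dwc:locationID")]
  loc_types <- d$object[d$subject == loc &
                          d$predicate == expand_curie("rdf:type")]
  expect_true(all(expand_curie(c("dwc:Location", "dcterms:Location"))
                  %in% loc_types))
  holo <- oracle_typed(res$doc, "openbiodiv:HolotypeDescription")
  expect_length(holo, 1L)
  expect_true(any(d$subject == res$iri &
                    d$predicate == expand_curie("po:contains") &
                    d$object == holo))
  # empty materials: typed section only, no companion records
  ctx$node_key <- "k|/t/mat2"
  res2 <- make_materials(list(), ctx, st)
  d2 <- tibble::as_tibble(res2$doc)
  expect_false(any(expand_curie(c("dwc:occurrenceID", "dwc:eventID"))
                   %in% d2$predicate))
  expect_true(expand_curie("openbiodiv:MaterialsExamined") %in% d2$object)
})

test_that("institutions attach codes to the treatment and reuse registry IRIs", {
  st <- id_store(deterministic = TRUE)
  treatment <- get_or_mint(st, "treatment", "k|t1")
  ctx <- list(graph_iri = frag, node_key = "k|/t/m/inst",
              parent_chain = list(
                list(iri = "http://openbiodiv.net/A", resource_type = "article"),
                list(iri = treatment, resource_type = "treatment"),
                list(iri = "http://openbiodiv.net/M", resource_type = "materials")))
  res <- make_institution(
    list(name = "Museu Nacional de Rio de Janeiro (MNRJ)", code = "MNRJ",
         collection_code = "MNRJ-ENT",
         registry_id = "http://grbio.org/cool/zi1i-a0b5"), ctx, st)
  expect_equal(res$iri, "http://grbio.org/cool/zi1i-a0b5")
  d <- tibble::as_tibble(res$doc)
  expect_true(expand_curie("openbiodiv:GRSciCollInstitution") %in% d$object)
  expect_true(any(d$subject == treatment &
                    d$predicate == expand_curie("dwc:institutionID") &
                    d$object == res$iri))
  expect_true(any(d$subject == treatment &
                    d$predicate == expand_curie("dwc:institutionCode") &
                    d$object == "MNRJ"))
  # name-only institution: typed, no codes on the treatment
  res2 <- make_institution(list(name = "Small Museum"), ctx, st)
  d2 <- tibble::as_tibble(res2$doc)
  expect_true(is_instance_iri(res2$iri))
  expect_false(expand_curie("dwc:institutionCode") %in% d2$predicate)
  # same institution again: identical IRI
  res3 <- make_institution(list(name = "Small Museum"), ctx, st)
  expect_identical(res3$iri, res2$iri)
  expect_error(make_institution(list(), ctx, st), "name")
})

test_that("external identifiers are typed per scheme and linked from the section", {
  st <- id_store(deterministic = TRUE)
  ctx <- list(graph_iri = frag, node_key = "k|/m/id",
              parent_chain = list(list(iri = "http://openbiodiv.net/M",
                                       resource_type = "materials")))
  res <- make_external_identifier(list(scheme = "genbank",
                                       value = "MG779236"), ctx, st)
  d <- tibble::as_tibble(res$doc)
  expect_true(expand_curie("datacite:ResourceIdentifier") %in% d$object)
  expect_true(any(d$predicate ==
                    expand_curie("datacite:usesIdentifierScheme") &
                    d$object == expand_curie("datacite:genbank")))
  expect_true(any(d$predicate ==
                    expand_curie("openbiodiv:mentionsIdentifier")))
  res2 <- make_external_identifier(
    list(scheme = "orcid", value = "0000-0003-4389-4270"), ctx, st)
  d2 <- tibble::as_tibble(res2$doc)
  expect_equal(res2$iri, "https://orcid.org/0000-0003-4389-4270")
  expect_true(expand_curie("datacite:PersonalIdentifier") %in% d2$object)
  expect_error(make_external_identifier(list(scheme = "mystery",
                                             value = "1"), ctx, st),
               "scheme")
  expect_warning(
    res3 <- make_external_identifier(list(scheme = "genbank"), ctx, st),
    "empty")
  expect_null(res3$iri)
})

test_that("containment closure is bidirectional on whole conversions", {
  for (gen in list(gen_taxpub, gen_taxonx)) {
    fx <- gen(fixture_config(seed = 13))
    dialect <- if (identical(gen, gen_taxpub)) "taxpub" else "taxonx"
    doc <- parse_article(fx$xml, dialect, id_store(), quiet = TRUE)
    d <- tibble::as_tibble(doc)
    fwd <- d[d$predicate == expand_curie("po:contains"), ]
    bwd <- d[d$predicate == expand_curie("po:isContainedBy"), ]
    expect_gt(nrow(fwd), 0L)
    expect_setequal(paste(fwd$subject, fwd$object),
                    paste(bwd$object, bwd$subject))
  }
})
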