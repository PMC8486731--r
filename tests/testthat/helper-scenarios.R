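# Shared test scenarios: a nomenclatural validity scenario builder and a
# three-article query corpus with backbone, built once per test run.

scenario_graph_iri <- "http://openbiodiv.net/570F0E79-5632-FF88-A155-73625E50C567"

name_node <- function(q, st, label) {
  n <- get_or_mint(st, "scientific_name", label)
  dplyr::bind_rows(
    rdf_quads(scenario_graph_iri, n, "rdf:type", iri("openbiodiv:ScientificName")),
    rdf_quads(scenario_graph_iri, n, "rdfs:label", lit(label)))
}

validity_scenario <- function(has_edge, has_loop, later_revalidation) {
  st <- id_store(deterministic = TRUE)
  q <- list(name_node(NULL, st, "Aus focus"),
            name_node(NULL, st, "Bus target"))
  a <- get_or_mint(st, "scientific_name", "Aus focus")
  b <- get_or_mint(st, "scientific_name", "Bus target")
  U <- "http://openbiodiv.net/Updates"
  if (has_edge) {
    q <- c(q, list(rdf_quads(U, a, "openbiodiv:replacementName", iri(b))))
    if (has_loop) {
      q <- c(q, list(rdf_quads(U, b, "openbiodiv:replacementName",
                               iri(a))))
    }
  } else if (has_loop) {
    # a loop elsewhere in the graph, not through the focus name
    c1 <- get_or_mint(st, "scientific_name", "Cus alius")
    q <- c(q, list(name_node(NULL, st, "Cus alius"),
                   rdf_quads(U, b, "openbiodiv:replacementName", iri(c1)),
                   rdf_quads(U, c1, "openbiodiv:replacementName", iri(b))))
  }
  # an unavailable usage of the focus name in an article dated 2010
  art1 <- get_or_mint(st, "article", "art1")
  tnu_u <- get_or_mint(st, "tnu", "tu")
  q <- c(q, list(
    rdf_quads(scenario_graph_iri, art1, "rdf:type", iri("fabio:JournalArticle")),
    rdf_quads(scenario_graph_iri, art1, "prism:publicationDate",
              lit("2010-01-01", datatype = "xsd:date")),
    rdf_quads(scenario_graph_iri, art1, "po:contains", iri(tnu_u)),
    rdf_quads(scenario_graph_iri, tnu_u, "rdf:type", iri("openbiodiv:TaxonomicNameUsage")),
    rdf_quads(scenario_graph_iri, tnu_u, "pkm:mentions", iri(a)),
    rdf_quads(scenario_graph_iri, tnu_u, "dwciri:taxonomicStatus",
              iri("openbiodiv:UnavailableName"))))
  if (later_revalidation) {
    art2 <- get_or_mint(st, "article", "art2")
    tnu_a <- get_or_mint(st, "tnu", "ta")
    q <- c(q, list(
      rdf_quads(scenario_graph_iri, art2, "rdf:type", iri("fabio:JournalArticle")),
      rdf_quads(scenario_graph_iri, art2, "prism:publicationDate",
                lit("2015-06-01", datatype = "xsd:date")),
      rdf_quads(scenario_graph_iri, art2, "po:contains", iri(tnu_a)),
      rdf_quads(scenario_graph_iri, tnu_a, "rdf:type",
                iri("openbiodiv:TaxonomicNameUsage")),
      rdf_quads(scenario_graph_iri, tnu_a, "pkm:mentions", iri(a)),
      rdf_quads(scenario_graph_iri, tnu_a, "dwciri:taxonomicStatus",
                iri("openbiodiv:AvailableName"))))
  }
  rdf_doc(dplyr::bind_rows(q))
}

query_corpus <- local({
  st <- id_store(deterministic = TRUE)
  # one author pool: author 1 appears on all three articles, author 2 on
  # two, author 3 on one -- a known productivity ranking
  cfgs <- list(
    fixture_config(seed = 201, statuses = c("1" = "sp. nov."),
                   author_seed = 777L),
    fixture_config(seed = 202, n_authors = 2L, author_seed = 777L),
    fixture_config(seed = 203, n_authors = 1L, author_seed = 777L)
  )
  fx <- lapply(cfgs, gen_taxpub)
  docs <- lapply(fx, function(f) {
    parse_article(f$xml, "taxpub", st, quiet = TRUE)
  })
  genus1 <- strsplit(fx[[1]]$truth$name_labels[[1]], " ")[[1]][1]
  fam1 <- paste0(genus1, "idae")
  tsv <- paste(
    paste("taxonID", "parentNameUsageID", "canonicalName", "taxonRank",
          "taxonomicStatus", "genus", "family", sep = "\t"),
    paste("100", "", fam1, "family", "accepted", "", fam1, sep = "\t"),
    paste("200", "100", genus1, "genus", "accepted", genus1, fam1,
          sep = "\t"),
    sep = "\n")
  backbone <- import_backbone(tsv, "GBIF Secretariat (2019)",
                              "F1DD0CF0-217D-422B-BAA4-58901976D7B4",
                              quiet = TRUE)
  all <- postprocess_graph(
    rdf_union(docs[[1]], docs[[2]], docs[[3]], backbone))$doc
  list(doc = all, fx = fx, genus1 = genus1, fam1 = fam1)
})
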