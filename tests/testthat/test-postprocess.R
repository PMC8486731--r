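# helper: build a minimal nomenclatural graph directly from quads
G <- "http://openbiodiv.net/570F0E79-5632-FF88-A155-73625E50C567"

mini_graph <- function(n_cited = 1L, status = "openbiodiv:ReplacementName",
                       cited_rank = "species") {
  st <- id_store(deterministic = TRUE)
  q <- list()
  add <- function(...) q[[length(q) + 1L]] <<- rdf_quads(G, ...)
  nom <- get_or_mint(st, "nomenclature", "n1")
  add(nom, "rdf:type", iri("openbiodiv:NomenclatureSection"))
  tnu1 <- get_or_mint(st, "tnu", "t1")
  add(tnu1, "rdf:type", iri("openbiodiv:TaxonomicNameUsage"))
  add(nom, "po:contains", iri(tnu1))
  name1 <- get_or_mint(st, "scientific_name", "Aus primus")
  add(name1, "rdf:type", iri("openbiodiv:ScientificName"))
  add(name1, "rdfs:label", lit("Aus primus"))
  add(name1, "dwc:verbatimTaxonRank", lit("species"))
  add(tnu1, "pkm:mentions", iri(name1))
  if (!is.null(status)) {
    add(tnu1, "dwciri:taxonomicStatus", iri(status))
  }
  cl <- get_or_mint(st, "citations_list", "cl1")
  add(cl, "rdf:type", iri("openbiodiv:NomenclatureCitationsList"))
  add(nom, "po:contains", iri(cl))
  for (i in seq_len(n_cited)) {
    cit <- get_or_mint(st, "citation", paste0("c", i))
    add(cl, "po:contains", iri(cit))
    tnu2 <- get_or_mint(st, "tnu", paste0("t2-", i))
    add(tnu2, "rdf:type", iri("openbiodiv:TaxonomicNameUsage"))
    add(cit, "po:contains", iri(tnu2))
    name2 <- get_or_mint(st, "scientific_name", paste0("Bus cited", i))
    add(name2, "rdf:type", iri("openbiodiv:ScientificName"))
    add(name2, "rdfs:label", lit(paste0("Bus cited", i)))
    add(name2, "dwc:verbatimTaxonRank", lit(cited_rank))
    add(tnu2, "pkm:mentions", iri(name2))
  }
  rdf_doc(dplyr::bind_rows(q))
}

test_that("the replacement rule matches the printed join shape exactly", {
  doc <- mini_graph()
  edges <- apply_replacement_rule(doc)
  expect_equal(nrow(edges), 1L)
  labels <- oracle_lit(doc, "rdfs:label")
  expect_equal(labels$v[labels$s == edges$from_name], "Bus cited1")
  expect_equal(labels$v[labels$s == edges$to_name], "Aus primus")
  # no replacement statuses anywhere: zero edges
  expect_equal(nrow(apply_replacement_rule(mini_graph(status = NULL))), 0L)
  expect_equal(nrow(apply_replacement_rule(
    mini_graph(status = "openbiodiv:TaxonomicDiscovery"))), 0L)
  # rank mismatch blocks the shared-variable join
  expect_equal(nrow(apply_replacement_rule(
    mini_graph(cited_rank = "genus"))), 0L)
})

test_that("update rules agree with brute-force enumeration on seeded fixtures", {
  for (seed in seq_len(20)) {
    cfg <- fixture_config(
      seed = seed,
      n_treatments = 1L + (seed %% 3L),
      n_citations_per_nomenclature = 1L + (seed %% 2L),
      statuses = stats::setNames(
        c("comb. nov.", "sp. nov."),
        as.character(c(1L + (seed %% 2L), 3L))))
    gen <- if (seed %% 2L == 0L) gen_taxpub else gen_taxonx
    dialect <- if (seed %% 2L == 0L) "taxpub" else "taxonx"
    fx <- gen(cfg)
    doc <- parse_article(fx$xml, dialect, id_store(), quiet = TRUE)
    repl <- apply_replacement_rule(doc)
    rel <- apply_related_rule(doc)
    expect_identical(edges_as_keys(repl), oracle_replacement(doc),
                     info = paste("replacement seed", seed))
    expect_identical(edges_as_keys(rel), oracle_related(doc),
                     info = paste("related seed", seed))
  }
})

test_that("a section with k distinct names yields k(k-1) related edges", {
  for (k_minus_1 in c(0L, 1L, 2L, 3L)) {
    cfg <- fixture_config(seed = 100 + k_minus_1, n_treatments = 1L,
                          n_names = 6L,
                          n_citations_per_nomenclature = k_minus_1,
                          statuses = character(0))
    doc <- parse_article(gen_taxpub(cfg)$xml, "taxpub", id_store(),
                         quiet = TRUE)
    k <- k_minus_1 + 1L
    expect_equal(nrow(apply_related_rule(doc)), k * (k - 1L))
  }
})

test_that("update rules are idempotent and edges live in the Updates graph", {
  cfg <- fixture_config(seed = 31, statuses = c("1" = "comb. nov."))
  doc <- parse_article(gen_taxpub(cfg)$xml, "taxpub", id_store(),
                       quiet = TRUE)
  pp1 <- postprocess_graph(doc)
  expect_gt(nrow(pp1$replacement) + nrow(pp1$related), 0L)
  d <- tibble::as_tibble(pp1$doc)
  upd <- d[d$graph == "http://openbiodiv.net/Updates", ]
  expect_equal(nrow(upd), nrow(pp1$replacement) + nrow(pp1$related))
  expect_true(all(upd$predicate %in%
                    expand_curie(c("openbiodiv:replacementName",
                                   "openbiodiv:relatedName"))))
  pp2 <- postprocess_graph(pp1$doc)
  expect_equal(nrow(pp2$doc), nrow(pp1$doc))
})

# --- validity ---------------------------------------------------------------

test_that("replacement detection distinguishes one-step and transitive modes", {
  # chain A -> B: replaced in both modes
  doc <- validity_scenario(TRUE, FALSE, FALSE)
  expect_true(is_replaced(doc, "Aus focus", mode = "one_step"))
  expect_true(is_replaced(doc, "Aus focus", mode = "transitive"))
  # cycle A -> B -> A: both modes say no
  doc2 <- validity_scenario(TRUE, TRUE, FALSE)
  expect_false(is_replaced(doc2, "Aus focus", mode = "one_step"))
  expect_false(is_replaced(doc2, "Aus focus", mode = "transitive"))
  # no outgoing edge
  doc3 <- validity_scenario(FALSE, FALSE, FALSE)
  expect_false(is_replaced(doc3, "Aus focus", mode = "one_step"))
  expect_false(is_replaced(doc3, "Aus focus", mode = "transitive"))
  expect_warning(is_replaced(doc3, "No such name"), "no scientific name")
})

test_that("unavailability respects the strict later-revalidation comparison", {
  expect_true(is_unavailable(validity_scenario(FALSE, FALSE, FALSE),
                             "Aus focus"))
  expect_false(is_unavailable(validity_scenario(FALSE, FALSE, TRUE),
                              "Aus focus"))
  # revalidation dated before the invalidation does not help
  doc <- validity_scenario(FALSE, FALSE, TRUE)
  d <- tibble::as_tibble(doc)
  d$object[d$object == "2015-06-01"] <- "2005-06-01"
  expect_true(is_unavailable(rdf_doc(d), "Aus focus"))
})

test_that("the validity verdict matches the prose truth table on all 8 combinations", {
  for (has_edge in c(FALSE, TRUE)) {
    for (has_loop in c(FALSE, TRUE)) {
      for (later in c(FALSE, TRUE)) {
        doc <- validity_scenario(has_edge, has_loop, later)
        v <- check_validity(doc, "Aus focus")
        replaced_expected <- has_edge && !has_loop
        unavailable_expected <- !later
        expect_equal(v$replaced, replaced_expected,
                     info = paste(has_edge, has_loop, later))
        expect_equal(v$unavailable, unavailable_expected,
                     info = paste(has_edge, has_loop, later))
        expect_equal(v$valid,
                     !(replaced_expected || unavailable_expected))
      }
    }
  }
})

test_that("containment closure equals the loop-based oracle", {
  fx <- gen_taxpub(fixture_config(seed = 19))
  doc <- parse_article(fx$xml, "taxpub", id_store(), quiet = TRUE)
  ours <- containment_closure(doc)
  oracle <- oracle_contains_closure(doc)
  expect_setequal(paste(ours$ancestor, ours$descendant),
                  paste(oracle$ancestor, oracle$descendant))
})
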