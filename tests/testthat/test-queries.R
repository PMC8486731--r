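# One purpose-built corpus exercises the whole catalogue: three articles
# sharing author 1 (same seeded author pool), a backbone aligned with the
# first article's treated genus, and update rules applied.

test_that("the catalogue lists twelve queries with shipped SPARQL text", {
  cat_ <- query_catalogue()
  expect_equal(nrow(cat_), 12L)
  for (q in cat_$query_id) {
    txt <- query_sparql(q, list(doi = "D", genus = "G", family_label = "F",
                                institution_name = "N",
                                institution_code = "C"))
    expect_match(txt, "PREFIX", info = q)
    expect_false(grepl("\\{\\{", txt), info = q)
  }
  expect_error(run_query(query_corpus$doc, "lucene_fuzzy"), "unknown")
  expect_error(run_query(query_corpus$doc, "figures_of_article"),
               "doi")
})

test_that("author productivity ranks the shared author first", {
  out <- run_query(query_corpus$doc, "most_prolific_author")
  # oracle: count each author label over the fixtures' author lists
  authors <- unlist(lapply(query_corpus$fx,
                           function(f) unique(f$truth$author_labels)))
  oracle <- sort(table(authors), decreasing = TRUE)
  expect_equal(nrow(out), length(unique(authors)))
  expect_equal(out$npapers[1], 3L)
  expect_equal(out$name[1], names(oracle)[1])
  got <- stats::setNames(out$npapers, out$name)
  expect_equal(got[names(oracle)], stats::setNames(as.integer(oracle),
                                                   names(oracle)))
})

test_that("mention counts follow the fixtures' usage arithmetic", {
  fx1 <- query_corpus$fx[[1]]
  doc1 <- parse_article(fx1$xml, "taxpub", id_store(), quiet = TRUE)
  out <- run_query(doc1, "most_mentioned_name")
  # oracle: name 1 is used in abstract, treatment 1 nomenclature,
  # citation of treatment 6 (absent here), figure 1 - recompute by index
  cfg <- fx1$config
  n <- cfg$n_names
  counts <- stats::setNames(rep(0L, n), fx1$truth$name_labels)
  bump <- function(i) counts[i] <<- counts[i] + 1L
  bump(1)  # abstract
  bump(taxograph:::treat_name_idx(2L, n))  # introduction
  bump(taxograph:::treat_name_idx(3L, n))  # discussion
  for (t in seq_len(cfg$n_treatments)) {
    bump(taxograph:::treat_name_idx(t, n))
    for (i in seq_len(cfg$n_citations_per_nomenclature)) {
      bump(taxograph:::cited_name_idx(t, i, n))
    }
  }
  for (f in seq_len(cfg$n_figures)) {
    bump(taxograph:::figure_name_idx(f, n))
  }
  counts <- counts[counts > 0L]
  got <- stats::setNames(out$nmentions, out$name)
  expect_equal(got[names(counts)], counts)
  # binomial restriction keeps the same rows here (all names binomial)
  out2 <- run_query(doc1, "most_mentioned_species")
  expect_setequal(out2$label, names(counts))
  out3 <- run_query(doc1, "species_by_articles")
  expect_true(all(out3$narticles == 1L))
})

test_that("figure queries count figure containment only", {
  fx1 <- query_corpus$fx[[1]]
  doc1 <- parse_article(fx1$xml, "taxpub", id_store(), quiet = TRUE)
  out <- run_query(doc1, "names_in_figures")
  cfg <- fx1$config
  fig_names <- table(vapply(seq_len(cfg$n_figures), function(f) {
    fx1$truth$name_labels[taxograph:::figure_name_idx(f, cfg$n_names)]
  }, character(1)))
  expect_setequal(out$name, names(fig_names))
  got <- stats::setNames(out$nmentions, out$name)
  expect_equal(got[names(fig_names)],
               stats::setNames(as.integer(fig_names), names(fig_names)))
  figs <- run_query(doc1, "figures_of_article",
                    list(doi = fx1$truth$doi))
  expect_equal(nrow(figs), cfg$n_figures)
  expect_equal(nrow(run_query(doc1, "figures_of_article",
                              list(doi = "10.1/none"))), 0L)
})

test_that("discoveries join the backbone hierarchy to article statuses", {
  out <- run_query(query_corpus$doc, "taxonomic_discoveries",
                   list(family_label = query_corpus$fam1))
  expect_gt(nrow(out), 0L)
  expect_true(all(out$vgenus == query_corpus$genus1))
  expect_true(all(grepl(paste0("^", query_corpus$genus1, " "),
                        out$verbatim)))
  expect_equal(unique(out$date), query_corpus$fx[[1]]$truth$pub_date)
  # a family with no discoveries yields an empty table
  expect_equal(nrow(run_query(query_corpus$doc, "taxonomic_discoveries",
                              list(family_label = "Nullidae"))), 0L)
})

test_that("institution impact aggregates treatments, articles, names and usages", {
  out <- run_query(query_corpus$doc, "institution_impact",
                   list(institution_name =
                          "Museu Nacional de Rio de Janeiro (MNRJ)",
                        institution_code = "MNRJ"))
  expect_equal(nrow(out), 1L)
  # one matched treatment per article (the institution sits in
  # treatment 1's materials of every fixture)
  expect_equal(out$times_mentioned, 3L)
  expect_equal(out$articles, 3L)
  dois <- vapply(query_corpus$fx, function(f) f$truth$doi, character(1))
  expect_setequal(strsplit(out$doi_of_articles, ", ")[[1]], dois)
  expect_gte(out$number_of_tnus, 3L)
})

test_that("collector rows pair nomenclature names with occurrence records", {
  fx1 <- query_corpus$fx[[1]]
  out <- run_query(query_corpus$doc, "collectors_of_genus",
                   list(genus = query_corpus$genus1))
  expect_gt(nrow(out), 0L)
  expect_equal(unique(out$recorder), fx1$truth$collector)
  expect_equal(unique(out$eventDate), fx1$truth$event_date)
  expect_true(all(grepl(paste0("^", query_corpus$genus1), out$label)))
})

test_that("per-family institutional impact groups treatments by family", {
  out <- run_query(query_corpus$doc, "institution_impact_per_family")
  expect_gt(nrow(out), 0L)
  fams <- unlist(lapply(query_corpus$fx, function(f) {
    cfg <- f$config
    idx <- vapply(seq_len(cfg$n_treatments),
                  function(t) taxograph:::treat_name_idx(t, cfg$n_names),
                  integer(1))
    unname(f$truth$families[f$truth$name_labels[idx[1]]])
  }))
  # only treatment 1 of each article carries the institution
  expect_setequal(out$family, fams)
  expect_true(all(out$instName ==
                    "Museu Nacional de Rio de Janeiro (MNRJ)"))
})

test_that("holotype-genomics rows link accession, institution and treatment name", {
  out <- run_query(query_corpus$doc, "holotypes_genomics")
  expect_equal(sort(unique(out$genomicLabel)), "MG779236")
  expect_true(all(out$system == expand_curie("datacite:genbank")))
  expect_true(all(out$institution == "http://grbio.org/cool/zi1i-a0b5"))
  dois <- vapply(query_corpus$fx, function(f) f$truth$doi, character(1))
  expect_setequal(unique(out$doi), dois)
})

test_that("related-name listings carry both labels", {
  out <- run_query(query_corpus$doc, "related_names")
  expect_gt(nrow(out), 0L)
  expect_lte(nrow(out), 100L)
  expect_true(all(nzchar(out$label_1)) && all(nzchar(out$label_2)))
  expect_true(all(out$name_1 != out$name_2))
  # empty graph: empty table everywhere
  expect_equal(nrow(run_query(rdf_doc(), "related_names")), 0L)
  expect_equal(nrow(run_query(rdf_doc(), "most_prolific_author")), 0L)
})
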