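# The competency-query catalogue. Each query is implemented as a
# relational pipeline over the quad table; the equivalent SPARQL text
# (with {{param}} slots) ships under inst/queries/ for use against an
# external SPARQL 1.1 endpoint.

query_catalogue_ids <- c(
  "related_names",
  "most_prolific_author",
  "most_mentioned_name",
  "most_mentioned_species",
  "species_by_articles",
  "names_in_figures",
  "figures_of_article",
  "taxonomic_discoveries",
  "institution_impact",
  "collectors_of_genus",
  "institution_impact_per_family",
  "holotypes_genomics"
)

#' List the shipped competency queries
#'
#' @return Tibble with query ids, required parameters and the path of the
#'   shipped SPARQL text.
#' @export
query_catalogue <- function() {
  params <- list(
    related_names = character(0),
    most_prolific_author = character(0),
    most_mentioned_name = character(0),
    most_mentioned_species = character(0),
    species_by_articles = character(0),
    names_in_figures = character(0),
    figures_of_article = "doi",
    taxonomic_discoveries = "family_label",
    institution_impact = c("institution_name", "institution_code"),
    collectors_of_genus = "genus",
    institution_impact_per_family = character(0),
    holotypes_genomics = character(0)
  )
  tibble::tibble(
    query_id = query_catalogue_ids,
    params = vapply(query_catalogue_ids,
                    function(q) paste(params[[q]], collapse = ","),
                    character(1)),
    sparql_file = paste0(query_catalogue_ids, ".rq")
  )
}

#' Read the shipped SPARQL text of a catalogue query
#'
#' `{{param}}` slots are substituted from `params`.
#'
#' @param query_id A catalogue id (see [query_catalogue()]).
#' @param params Named list of parameter values.
#' @return SPARQL query string.
#' @export
query_sparql <- function(query_id, params = list()) {
  path <- system.file("queries", paste0(query_id, ".rq"),
                      package = "taxograph", mustWork = TRUE)
  text <- paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                collapse = "\n")
  for (nm in names(params)) {
    text <- gsub(paste0("{{", nm, "}}"), params[[nm]], text, fixed = TRUE)
  }
  text
}

need_param <- function(params, name, query_id) {
  if (is.null(params[[name]])) {
    stop("query '", query_id, "' requires parameter '", name, "'",
         call. = FALSE)
  }
  params[[name]]
}

sci_names_with <- function(d, require_binomial = FALSE) {
  sci <- type_subjects(d, "openbiodiv:ScientificName")
  labels <- lit_pairs(d, "rdfs:label")
  out <- dplyr::filter(labels, .data$subject %in% sci)
  out <- dplyr::select(out, name_iri = "subject", label = "value")
  if (require_binomial) {
    genus <- lit_pairs(d, "dwc:genus")
    species <- lit_pairs(d, "dwc:specificEpithet")
    out <- dplyr::inner_join(
      out, dplyr::select(genus, name_iri = "subject", genus = "value"),
      by = "name_iri", relationship = "many-to-many")
    out <- dplyr::inner_join(
      out, dplyr::select(species, name_iri = "subject",
                         species = "value"),
      by = "name_iri", relationship = "many-to-many")
  }
  dplyr::distinct(out)
}

#' Run a competency query over a quad document
#'
#' Evaluates one of the twelve shipped catalogue queries directly on the
#' quad table (no external SPARQL endpoint needed). Result columns follow
#' the SELECT clause of the shipped SPARQL text.
#'
#' @param doc A `triple_doc`.
#' @param query_id A catalogue id (see [query_catalogue()]).
#' @param params Named list binding the query's parameter slots (e.g.
#'   `doi`, `genus`, `family_label`, `institution_code`).
#' @return A tibble of solutions (empty when nothing matches).
#' @export
run_query <- function(doc, query_id, params = list()) {
  if (!query_id %in% query_catalogue_ids) {
    stop("unknown query id '", query_id, "'; see query_catalogue()",
         call. = FALSE)
  }
  d <- tibble::as_tibble(doc)
  switch(query_id,
    related_names = q_related_names(d),
    most_prolific_author = q_most_prolific_author(d),
    most_mentioned_name = q_most_mentioned_name(d),
    most_mentioned_species = q_most_mentioned_species(d),
    species_by_articles = q_species_by_articles(d),
    names_in_figures = q_names_in_figures(d),
    figures_of_article = q_figures_of_article(
      d, need_param(params, "doi", query_id)),
    taxonomic_discoveries = q_taxonomic_discoveries(
      d, need_param(params, "family_label", query_id)),
    institution_impact = q_institution_impact(
      d, need_param(params, "institution_name", query_id),
      need_param(params, "institution_code", query_id)),
    collectors_of_genus = q_collectors_of_genus(
      d, need_param(params, "genus", query_id)),
    institution_impact_per_family = q_institution_impact_per_family(d),
    holotypes_genomics = q_holotypes_genomics(d)
  )
}

q_related_names <- function(d) {
  edges <- pred_pairs(d, "openbiodiv:relatedName")
  labels <- lit_pairs(d, "rdfs:label")
  j <- dplyr::inner_join(
    dplyr::select(edges, name_1 = "subject", name_2 = "object"),
    dplyr::select(labels, name_1 = "subject", label_1 = "value"),
    by = "name_1", relationship = "many-to-many")
  j <- dplyr::inner_join(
    j, dplyr::select(labels, name_2 = "subject", label_2 = "value"),
    by = "name_2", relationship = "many-to-many")
  utils::head(dplyr::distinct(j), 100L)
}

q_most_prolific_author <- function(d) {
  persons <- type_subjects(d, "foaf:Person")
  labels <- lit_pairs(d, "rdfs:label")
  papers <- type_subjects(d, "fabio:ResearchPaper")
  creator <- pred_pairs(d, "dcterms:creator")
  j <- dplyr::filter(creator, .data$subject %in% papers,
                     .data$object %in% persons)
  j <- dplyr::inner_join(
    dplyr::select(j, paper = "subject", author = "object"),
    dplyr::select(labels, author = "subject", name = "value"),
    by = "author", relationship = "many-to-many")
  if (nrow(j) == 0L) {
    return(tibble::tibble(name = character(0), npapers = integer(0)))
  }
  out <- dplyr::summarise(
    dplyr::group_by(j, .data$author),
    name = min(.data$name),
    npapers = dplyr::n_distinct(.data$paper),
    .groups = "drop")
  dplyr::select(dplyr::arrange(out, dplyr::desc(.data$npapers),
                               .data$name),
                name = "name", npapers = "npapers")
}

q_most_mentioned_name <- function(d) {
  names_ <- sci_names_with(d)
  mentions <- pred_pairs(d, "pkm:mentions")
  j <- dplyr::inner_join(
    dplyr::select(mentions, tnu = "subject", name_iri = "object"),
    names_, by = "name_iri", relationship = "many-to-many")
  if (nrow(j) == 0L) {
    return(tibble::tibble(name = character(0), nmentions = integer(0)))
  }
  out <- dplyr::summarise(
    dplyr::group_by(j, .data$name_iri),
    name = min(.data$label),
    nmentions = dplyr::n_distinct(.data$tnu),
    .groups = "drop")
  dplyr::select(dplyr::arrange(out, dplyr::desc(.data$nmentions),
                               .data$name),
                name = "name", nmentions = "nmentions")
}

q_most_mentioned_species <- function(d) {
  names_ <- sci_names_with(d, require_binomial = TRUE)
  mentions <- pred_pairs(d, "pkm:mentions")
  j <- dplyr::inner_join(
    dplyr::select(mentions, tnu = "subject", name_iri = "object"),
    names_, by = "name_iri", relationship = "many-to-many")
  if (nrow(j) == 0L) {
    return(tibble::tibble(label = character(0), nmentions = integer(0)))
  }
  out <- dplyr::summarise(
    dplyr::group_by(j, .data$name_iri, .data$label),
    nmentions = dplyr::n_distinct(.data$tnu),
    .groups = "drop")
  dplyr::select(dplyr::arrange(out, dplyr::desc(.data$nmentions),
                               .data$label),
                label = "label", nmentions = "nmentions")
}

q_species_by_articles <- function(d) {
  names_ <- sci_names_with(d, require_binomial = TRUE)
  mentions <- pred_pairs(d, "pkm:mentions")
  articles <- type_subjects(d, "fabio:JournalArticle")
  closure <- containment_closure(d)
  j <- dplyr::inner_join(
    dplyr::select(mentions, tnu = "subject", name_iri = "object"),
    names_, by = "name_iri", relationship = "many-to-many")
  j <- dplyr::inner_join(
    j,
    dplyr::select(dplyr::filter(closure, .data$ancestor %in% articles),
                  article = "ancestor", tnu = "descendant"),
    by = "tnu", relationship = "many-to-many")
  if (nrow(j) == 0L) {
    return(tibble::tibble(n = character(0), narticles = integer(0)))
  }
  out <- dplyr::summarise(
    dplyr::group_by(j, .data$name_iri),
    n = min(.data$label),
    narticles = dplyr::n_distinct(.data$article),
    .groups = "drop")
  dplyr::select(dplyr::arrange(out, dplyr::desc(.data$narticles),
                               .data$n),
                n = "n", narticles = "narticles")
}

q_names_in_figures <- function(d) {
  names_ <- sci_names_with(d)
  mentions <- pred_pairs(d, "pkm:mentions")
  figures <- type_subjects(d, "doco:Figure")
  contains <- pred_pairs(d, "po:contains")
  j <- dplyr::inner_join(
    dplyr::select(mentions, tnu = "subject", name_iri = "object"),
    names_, by = "name_iri", relationship = "many-to-many")
  j <- dplyr::inner_join(
    j,
    dplyr::select(dplyr::filter(contains, .data$subject %in% figures),
                  figure = "subject", tnu = "object"),
    by = "tnu", relationship = "many-to-many")
  if (nrow(j) == 0L) {
    return(tibble::tibble(name = character(0), nmentions = integer(0)))
  }
  out <- dplyr::summarise(
    dplyr::group_by(j, .data$name_iri),
    name = max(.data$label),
    nmentions = dplyr::n_distinct(.data$figure),
    .groups = "drop")
  dplyr::select(dplyr::arrange(out, dplyr::desc(.data$nmentions),
                               .data$name),
                name = "name", nmentions = "nmentions")
}

q_figures_of_article <- function(d, doi) {
  dois <- lit_pairs(d, "prism:doi")
  articles <- intersect(type_subjects(d, "fabio:JournalArticle"),
                        dois$subject[dois$value == doi])
  figures <- type_subjects(d, "doco:Figure")
  contains <- pred_pairs(d, "po:contains")
  f <- dplyr::filter(contains, .data$subject %in% articles,
                     .data$object %in% figures)
  dplyr::distinct(dplyr::select(f, f = "object"))
}

q_taxonomic_discoveries <- function(d, family_label) {
  labels <- lit_pairs(d, "rdfs:label")
  fam_names <- labels$subject[labels$value == family_label]
  sci_link <- pred_pairs(d, "openbiodiv:scientificName")
  fam_concepts <- sci_link$subject[sci_link$object %in% fam_names]
  broader <- pred_pairs(d, "skos:broader")
  children <- broader$subject[broader$object %in% fam_concepts]
  child_names <- dplyr::filter(sci_link, .data$subject %in% children)
  genera <- lit_pairs(d, "dwc:genus")
  child_genera <- dplyr::inner_join(
    dplyr::select(child_names, concept = "subject", sn = "object"),
    dplyr::select(genera, sn = "subject", vgenus = "value"),
    by = "sn", relationship = "many-to-many")
  status <- pred_pairs(d, "dwciri:taxonomicStatus")
  disc <- expand_curie("openbiodiv:TaxonomicDiscovery")
  disc_tnus <- status$subject[status$object == disc]
  mentions <- pred_pairs(d, "pkm:mentions")
  m <- dplyr::filter(mentions, .data$subject %in% disc_tnus)
  name_genera <- dplyr::inner_join(
    dplyr::select(m, tnu = "subject", name = "object"),
    dplyr::select(genera, name = "subject", vgenus = "value"),
    by = "name", relationship = "many-to-many")
  j <- dplyr::inner_join(name_genera,
                         dplyr::distinct(dplyr::select(child_genera,
                                                       vgenus = "vgenus")),
                         by = "vgenus")
  j <- dplyr::inner_join(
    j, dplyr::select(labels, name = "subject", verbatim = "value"),
    by = "name", relationship = "many-to-many")
  ad <- tnu_article_dates(d)
  j <- dplyr::inner_join(
    j, dplyr::select(ad, tnu = "tnu", article = "article",
                     date = "date_str"),
    by = "tnu", relationship = "many-to-many")
  dplyr::distinct(dplyr::select(j, verbatim = "verbatim",
                                vgenus = "vgenus", article = "article",
                                date = "date"))
}

treatment_tnus_1or2 <- function(d) {
  treatments <- type_subjects(d, "openbiodiv:Treatment")
  closure <- containment_closure(d, max_steps = 2L)
  dplyr::select(
    dplyr::filter(closure, .data$ancestor %in% treatments),
    treatment = "ancestor", tnu = "descendant")
}

q_institution_impact <- function(d, institution_name, institution_code) {
  treatments <- type_subjects(d, "openbiodiv:Treatment")
  match_preds <- dplyr::bind_rows(
    lit_pairs(d, "openbiodiv:institutionName"),
    lit_pairs(d, "dwc:institutionCode"),
    lit_pairs(d, "dwc:collectionCode"))
  hits <- dplyr::filter(match_preds, .data$subject %in% treatments,
                        .data$value %in% c(institution_code,
                                           institution_name))
  hit_treatments <- unique(hits$subject)
  tt <- dplyr::filter(treatment_tnus_1or2(d),
                      .data$treatment %in% hit_treatments)
  tnus <- type_subjects(d, "openbiodiv:TaxonomicNameUsage")
  tt <- dplyr::filter(tt, .data$tnu %in% tnus)
  mentions <- pred_pairs(d, "pkm:mentions")
  names_ <- sci_names_with(d)
  m <- dplyr::inner_join(
    tt, dplyr::select(mentions, tnu = "subject", name_iri = "object"),
    by = "tnu", relationship = "many-to-many")
  m <- dplyr::inner_join(m, names_, by = "name_iri",
                         relationship = "many-to-many")
  contains <- pred_pairs(d, "po:contains")
  articles <- type_subjects(d, "fabio:JournalArticle")
  dois <- lit_pairs(d, "prism:doi")
  at <- dplyr::filter(contains, .data$subject %in% articles,
                      .data$object %in% hit_treatments)
  at <- dplyr::inner_join(
    dplyr::select(at, article = "subject", treatment = "object"),
    dplyr::select(dois, article = "subject", doi = "value"),
    by = "article", relationship = "many-to-many")
  m <- dplyr::inner_join(m, at, by = "treatment",
                         relationship = "many-to-many")
  if (nrow(m) == 0L) {
    return(tibble::tibble(
      institution_name = character(0), times_mentioned = integer(0),
      articles = integer(0), doi_of_articles = character(0),
      names_mentioned = character(0), number_of_taxa = integer(0),
      number_of_tnus = integer(0)))
  }
  tibble::tibble(
    institution_name = institution_name,
    times_mentioned = dplyr::n_distinct(m$treatment),
    articles = dplyr::n_distinct(m$article),
    doi_of_articles = paste(sort(unique(m$doi)), collapse = ", "),
    names_mentioned = paste(sort(unique(m$label)), collapse = ", "),
    number_of_taxa = dplyr::n_distinct(m$name_iri),
    number_of_tnus = dplyr::n_distinct(m$tnu)
  )
}

q_collectors_of_genus <- function(d, genus) {
  contains <- pred_pairs(d, "po:contains")
  treatments <- type_subjects(d, "openbiodiv:Treatment")
  materials <- type_subjects(d, "openbiodiv:MaterialsExamined")
  noms <- type_subjects(d, "openbiodiv:NomenclatureSection")
  t_m <- dplyr::filter(contains, .data$subject %in% treatments,
                       .data$object %in% materials)
  t_n <- dplyr::filter(contains, .data$subject %in% treatments,
                       .data$object %in% noms)
  tm <- dplyr::inner_join(
    dplyr::select(t_m, treatment = "subject", materials = "object"),
    dplyr::select(t_n, treatment = "subject", nomenclature = "object"),
    by = "treatment", relationship = "many-to-many")
  occ <- pred_pairs(d, "dwc:occurrenceID")
  rec <- lit_pairs(d, "dwc:recordedBy")
  ev <- pred_pairs(d, "dwc:eventID")
  evd <- lit_pairs(d, "dwc:eventDate")
  tm <- dplyr::inner_join(
    tm, dplyr::select(occ, materials = "subject", occurrence = "object"),
    by = "materials", relationship = "many-to-many")
  tm <- dplyr::inner_join(
    tm, dplyr::select(rec, occurrence = "subject", recorder = "value"),
    by = "occurrence", relationship = "many-to-many")
  tm <- dplyr::inner_join(
    tm, dplyr::select(ev, materials = "subject", event = "object"),
    by = "materials", relationship = "many-to-many")
  tm <- dplyr::inner_join(
    tm, dplyr::select(evd, event = "subject", eventDate = "value"),
    by = "event", relationship = "many-to-many")
  mentions <- pred_pairs(d, "pkm:mentions")
  nm <- dplyr::inner_join(
    dplyr::select(dplyr::filter(contains,
                                .data$subject %in% tm$nomenclature),
                  nomenclature = "subject", tnu = "object"),
    dplyr::select(mentions, tnu = "subject", name = "object"),
    by = "tnu", relationship = "many-to-many")
  genera <- lit_pairs(d, "dwc:genus")
  labels <- lit_pairs(d, "rdfs:label")
  nm <- dplyr::filter(
    nm, .data$name %in% genera$subject[genera$value == genus])
  nm <- dplyr::inner_join(
    nm, dplyr::select(labels, name = "subject", label = "value"),
    by = "name", relationship = "many-to-many")
  out <- dplyr::inner_join(tm, nm, by = "nomenclature",
                           relationship = "many-to-many")
  dplyr::distinct(dplyr::select(out, label = "label",
                                recorder = "recorder",
                                eventDate = "eventDate"))
}

q_institution_impact_per_family <- function(d) {
  mentions <- pred_pairs(d, "pkm:mentions")
  families <- lit_pairs(d, "dwc:family")
  m <- dplyr::inner_join(
    dplyr::select(mentions, tnu = "subject", name = "object"),
    dplyr::select(families, name = "subject", family = "value"),
    by = "name", relationship = "many-to-many")
  tt <- treatment_tnus_1or2(d)
  m <- dplyr::inner_join(m, tt, by = "tnu", relationship = "many-to-many")
  inst_link <- pred_pairs(d, "dwc:institutionID")
  insts <- type_subjects(d, "openbiodiv:Institution")
  inames <- lit_pairs(d, "openbiodiv:institutionName")
  il <- dplyr::filter(inst_link, .data$object %in% insts)
  m <- dplyr::inner_join(
    m, dplyr::select(il, treatment = "subject", inst = "object"),
    by = "treatment", relationship = "many-to-many")
  m <- dplyr::inner_join(
    m, dplyr::select(inames, inst = "subject", instName = "value"),
    by = "inst", relationship = "many-to-many")
  dplyr::summarise(
    dplyr::group_by(m, .data$family, .data$inst, .data$instName),
    treatments = dplyr::n_distinct(.data$treatment),
    .groups = "drop")
}

q_holotypes_genomics <- function(d) {
  scheme <- pred_pairs(d, "datacite:usesIdentifierScheme")
  wanted <- expand_curie(c("datacite:genbank", "datacite:boldsystems"))
  gids <- dplyr::filter(scheme, .data$object %in% wanted)
  labels <- lit_pairs(d, "rdfs:label")
  gids <- dplyr::inner_join(
    dplyr::select(gids, genomicIdentifier = "subject", system = "object"),
    dplyr::select(labels, genomicIdentifier = "subject",
                  genomicLabel = "value"),
    by = "genomicIdentifier", relationship = "many-to-many")
  mentions_id <- pred_pairs(d, "openbiodiv:mentionsIdentifier")
  materials <- type_subjects(d, "openbiodiv:MaterialsExamined")
  mi <- dplyr::filter(mentions_id, .data$subject %in% materials)
  j <- dplyr::inner_join(
    dplyr::select(mi, materialsExamined = "subject",
                  genomicIdentifier = "object"),
    gids, by = "genomicIdentifier", relationship = "many-to-many")
  contains <- pred_pairs(d, "po:contains")
  holo <- type_subjects(d, "openbiodiv:HolotypeDescription")
  has_holo <- dplyr::filter(contains, .data$object %in% holo)
  j <- dplyr::semi_join(
    j, dplyr::select(has_holo, materialsExamined = "subject"),
    by = "materialsExamined")
  treatments <- type_subjects(d, "openbiodiv:Treatment")
  t_m <- dplyr::filter(contains, .data$subject %in% treatments)
  j <- dplyr::inner_join(
    j, dplyr::select(t_m, treatment = "subject",
                     materialsExamined = "object"),
    by = "materialsExamined", relationship = "many-to-many")
  inst_link <- pred_pairs(d, "dwc:institutionID")
  j <- dplyr::inner_join(
    j, dplyr::select(inst_link, treatment = "subject",
                     institution = "object"),
    by = "treatment", relationship = "many-to-many")
  noms <- type_subjects(d, "openbiodiv:NomenclatureSection")
  t_n <- dplyr::filter(contains, .data$subject %in% treatments,
                       .data$object %in% noms)
  j <- dplyr::inner_join(
    j, dplyr::select(t_n, treatment = "subject", nomenclature = "object"),
    by = "treatment", relationship = "many-to-many")
  mentions <- pred_pairs(d, "pkm:mentions")
  n_t <- dplyr::inner_join(
    dplyr::select(dplyr::filter(contains,
                                .data$subject %in% t_n$object),
                  nomenclature = "subject", tnu = "object"),
    dplyr::select(mentions, tnu = "subject", name = "object"),
    by = "tnu", relationship = "many-to-many")
  n_t <- dplyr::inner_join(
    n_t, dplyr::select(labels, name = "subject", label = "value"),
    by = "name", relationship = "many-to-many")
  j <- dplyr::inner_join(j, n_t, by = "nomenclature",
                         relationship = "many-to-many")
  articles <- type_subjects(d, "fabio:JournalArticle")
  dois <- lit_pairs(d, "prism:doi")
  a_t <- dplyr::filter(contains, .data$subject %in% articles)
  a_t <- dplyr::inner_join(
    dplyr::select(a_t, article = "subject", treatment = "object"),
    dplyr::select(dois, article = "subject", doi = "value"),
    by = "article", relationship = "many-to-many")
  j <- dplyr::inner_join(j, a_t, by = "treatment",
                         relationship = "many-to-many")
  dplyr::distinct(dplyr::select(
    j, materialsExamined = "materialsExamined",
    genomicLabel = "genomicLabel", system = "system", name = "name",
    label = "label", institution = "institution", doi = "doi"))
}
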