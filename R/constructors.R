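# RDF constructors: one per resource type. Each takes the extracted atoms,
# a context (graph IRI, article IRI, ancestor chain) and the identifier
# store, and returns list(doc = triple_doc, iri = IRI of the resource it
# created). Containment is always materialized in both directions
# (po:contains / po:isContainedBy) instead of relying on triple-store
# inverse-property inference.

section_kind_classes <- c(
  title           = "doco:Title",
  abstract        = "sro:Abstract",
  keyword_group   = "openbiodiv:KeywordGroup",
  introduction    = "deo:Introduction",
  discussion      = "orb:Discussion",
  treatment       = "openbiodiv:Treatment",
  nomenclature    = "openbiodiv:NomenclatureSection",
  citations_list  = "openbiodiv:NomenclatureCitationsList",
  citation        = "deo:BibliographicReference",
  diagnosis       = "openbiodiv:DiagnosisSection",
  distribution    = "openbiodiv:DistributionSection",
  taxonomic_key   = "openbiodiv:TaxonomicKey",
  figure          = "doco:Figure",
  reference_list  = "doco:BibliographicReferenceList",
  reference       = "deo:BibliographicReference"
)

#' Status mapping table
#'
#' Maps nomenclatural status strings as printed in articles (e.g.
#' `"sp. nov."`, `"comb. nov."`, `"nomen dubium"`) to status class IRIs.
#' Shipped as an editable CSV; unknown statuses produce no status triple.
#'
#' @param path CSV with columns `status_text`, `status_class`; defaults to
#'   the shipped table.
#' @return Named character vector: status text -> expanded class IRI.
#' @export
default_status_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "status_mapping.csv",
                        package = "taxograph", mustWork = TRUE)
  }
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stats::setNames(expand_curie(tab$status_class), tab$status_text)
}

atom1 <- function(atoms, name) {
  v <- atoms[[name]]
  if (is.null(v) || length(v) == 0L) return(NULL)
  v <- v[nzchar(trimws(v))]
  if (length(v) == 0L) return(NULL)
  trimws(v[[1]])
}

atom_all <- function(atoms, name) {
  v <- atoms[[name]]
  if (is.null(v)) return(character(0))
  v <- trimws(v)
  v[nzchar(v)]
}

contain_quads <- function(graph, parent, child) {
  dplyr::bind_rows(
    rdf_quads(graph, child, "po:isContainedBy", iri(parent)),
    rdf_quads(graph, parent, "po:contains", iri(child))
  )
}

mint_structural <- function(store, resource_type, ctx) {
  get_or_mint(store, resource_type, ctx$node_key)
}

nearest_ancestor <- function(ctx, resource_type) {
  chain <- ctx$parent_chain
  if (is.null(chain) || length(chain) == 0L) return(NULL)
  types <- vapply(chain, `[[`, character(1), "resource_type")
  hits <- which(types == resource_type)
  if (length(hits) == 0L) return(NULL)
  chain[[max(hits)]]$iri
}

parent_iri_of <- function(ctx) {
  chain <- ctx$parent_chain
  if (is.null(chain) || length(chain) == 0L) return(NULL)
  chain[[length(chain)]]$iri
}

#' Construct the article resource
#'
#' The article is typed both `fabio:JournalArticle` (its concrete journal
#' expression) and `fabio:ResearchPaper` (the work it realizes) so that
#' queries phrased against either class succeed. DOI, title, publisher
#' (as a literal and as a minted agent resource) and the publication date
#' (as `xsd:date` when parseable) are attached when present.
#'
#' @param atoms Named list of extracted values (`doi`, `title`,
#'   `publisher`, `pub_date`).
#' @param ctx Construction context; may be NULL for fragment conversion.
#' @param store An [id_store()].
#' @return `list(doc, iri, graph)`.
#' @export
make_article <- function(atoms, ctx, store) {
  doi <- atom1(atoms, "doi")
  title <- atom1(atoms, "title")
  if (is.null(doi) && is.null(title)) {
    stop("article has neither a DOI nor a title and cannot be identified",
         call. = FALSE)
  }
  label <- if (!is.null(doi)) doi else title
  iri_a <- get_or_mint(store, "article", label,
                       metadata = if (!is.null(doi)) list(doi = doi))
  g <- iri_a
  q <- dplyr::bind_rows(
    rdf_quads(g, iri_a, "rdf:type", iri("fabio:JournalArticle")),
    rdf_quads(g, iri_a, "rdf:type", iri("fabio:ResearchPaper"))
  )
  if (!is.null(doi)) {
    q <- dplyr::bind_rows(q, rdf_quads(g, iri_a, "prism:doi", lit(doi)))
  }
  if (!is.null(title)) {
    q <- dplyr::bind_rows(
      q,
      rdf_quads(g, iri_a, "dc:title", lit(title)),
      rdf_quads(g, iri_a, "rdfs:label", lit(title))
    )
  }
  publisher <- atom1(atoms, "publisher")
  if (!is.null(publisher)) {
    agent <- get_or_mint(store, "agent", publisher)
    q <- dplyr::bind_rows(
      q,
      rdf_quads(g, iri_a, "dc:publisher", lit(publisher)),
      rdf_quads(g, iri_a, "dcterms:publisher", iri(agent)),
      rdf_quads(g, agent, "rdf:type", iri("foaf:Agent")),
      rdf_quads(g, agent, "rdfs:label", lit(publisher))
    )
  }
  pub_date <- atom1(atoms, "pub_date")
  if (!is.null(pub_date)) {
    if (grepl("^\\d{4}-\\d{2}-\\d{2}$", pub_date)) {
      q <- dplyr::bind_rows(
        q, rdf_quads(g, iri_a, "prism:publicationDate",
                     lit(pub_date, datatype = "xsd:date")))
    } else {
      warning("unparseable publication date kept as plain literal: '",
              pub_date, "'", call. = FALSE)
      q <- dplyr::bind_rows(
        q, rdf_quads(g, iri_a, "prism:publicationDate", lit(pub_date)))
    }
  }
  list(doc = rdf_doc(q), iri = iri_a, graph = g)
}

#' Construct a person (author) resource
#'
#' Persons are `foaf:Person` with full-name label, surname, affiliation
#' literals and an ORCID link via `datacite:hasIdentifier` when present;
#' institutional authors (a collaboration name, no surname) are typed
#' `foaf:Agent` instead. When the context carries an article IRI the
#' article is linked to the person via `dcterms:creator`.
#'
#' @inheritParams make_article
#' @return `list(doc, iri)`.
#' @export
make_person <- function(atoms, ctx, store) {
  g <- ctx$graph_iri %||% "openbiodiv:Fragments"
  surname <- atom1(atoms, "surname")
  given <- atom1(atoms, "given_names")
  inst_name <- atom1(atoms, "institution_name")
  if (is.null(surname) && is.null(given) && is.null(inst_name)) {
    stop("person node carries no name atom", call. = FALSE)
  }
  if (is.null(surname) && is.null(given)) {
    # institutional author
    a_iri <- get_or_mint(store, "person", inst_name)
    q <- dplyr::bind_rows(
      rdf_quads(g, a_iri, "rdf:type", iri("foaf:Agent")),
      rdf_quads(g, a_iri, "rdfs:label", lit(inst_name))
    )
  } else {
    label <- if (!is.null(given) && !is.null(surname) &&
                 grepl(paste0("\\b", surname, "$"), given)) {
      given
    } else {
      paste(c(given, surname), collapse = " ")
    }
    a_iri <- get_or_mint(store, "person", label)
    q <- dplyr::bind_rows(
      rdf_quads(g, a_iri, "rdf:type", iri("foaf:Person")),
      rdf_quads(g, a_iri, "rdfs:label", lit(label))
    )
    if (!is.null(surname)) {
      q <- dplyr::bind_rows(
        q, rdf_quads(g, a_iri, "foaf:surname", lit(surname)))
    }
    for (aff in atom_all(atoms, "affiliation")) {
      q <- dplyr::bind_rows(
        q, rdf_quads(g, a_iri, "openbiodiv:affiliation", lit(aff)))
    }
    orcid <- atom1(atoms, "orcid")
    if (!is.null(orcid)) {
      orcid_id <- sub("^https?://orcid\\.org/", "", orcid)
      orcid_iri <- paste0("https://orcid.org/", orcid_id)
      q <- dplyr::bind_rows(
        q, rdf_quads(g, a_iri, "datacite:hasIdentifier", iri(orcid_iri)))
    }
  }
  if (!is.null(ctx$article_iri)) {
    q <- dplyr::bind_rows(
      q, rdf_quads(g, ctx$article_iri, "dcterms:creator", iri(a_iri)))
  }
  list(doc = rdf_doc(q), iri = a_iri)
}

#' Construct a document-component section
#'
#' Emits the resource typed according to the data-type mapping (abstract
#' -> `sro:Abstract`, introduction -> `deo:Introduction`, treatment ->
#' `openbiodiv:Treatment`, figure -> `doco:Figure`, ...) and bidirectional
#' containment links to the immediate parent.
#'
#' @inheritParams make_article
#' @param kind Section kind; one of the names of the data-type mapping.
#' @return `list(doc, iri)`.
#' @export
make_section <- function(atoms, ctx, store, kind) {
  if (!kind %in% names(section_kind_classes)) {
    stop("unknown section kind '", kind, "'", call. = FALSE)
  }
  s_iri <- mint_structural(store, kind, ctx)
  g <- ctx$graph_iri
  q <- rdf_quads(g, s_iri, "rdf:type", iri(section_kind_classes[[kind]]))
  parent <- parent_iri_of(ctx)
  if (!is.null(parent)) {
    q <- dplyr::bind_rows(q, contain_quads(g, parent, s_iri))
  }
  text <- atom1(atoms, "text") %||% atom1(atoms, "caption")
  if (!is.null(text)) {
    q <- dplyr::bind_rows(q, rdf_quads(g, s_iri, "rdfs:label", lit(text)))
  }
  for (kw in atom_all(atoms, "keyword")) {
    q <- dplyr::bind_rows(
      q, rdf_quads(g, s_iri, "openbiodiv:keyword", lit(kw)))
  }
  ref_text <- atom1(atoms, "citation_text")
  if (!is.null(ref_text)) {
    q <- dplyr::bind_rows(
      q, rdf_quads(g, s_iri, "c4o:hasContent", lit(ref_text)))
  }
  list(doc = rdf_doc(q), iri = s_iri)
}

#' Construct a scientific-name resource
#'
#' The name is content-addressed by its regularized label (parts joined
#' by single spaces), so the same name in two articles resolves to one
#' IRI. Regularized (`reg`) part values take precedence over the
#' displayed text, which may be abbreviated. When a backbone match for
#' the label is configured, the name links to the backbone `-scName`
#' resource via `openbiodiv:hasGbifTaxon`.
#'
#' @inheritParams make_article
#' @return `list(doc, iri, label)`.
#' @export
make_scientific_name <- function(atoms, ctx, store) {
  part <- function(stem) {
    atom1(atoms, paste0(stem, "_reg")) %||%
      atom1(atoms, paste0(stem, "_verbatim"))
  }
  genus <- part("genus")
  species <- part("species")
  family <- part("family")
  parts <- c(genus, species)
  label <- if (length(parts) > 0L) {
    paste(parts, collapse = " ")
  } else if (!is.null(family)) {
    family
  } else {
    stop("scientific name without any regularized part", call. = FALSE)
  }
  label <- normalize_label(label)
  rank <- atom1(atoms, "rank") %||%
    (if (!is.null(species)) "species"
     else if (!is.null(genus)) "genus"
     else "family")
  g <- ctx$graph_iri %||% "openbiodiv:Fragments"
  n_iri <- get_or_mint(store, "scientific_name", label)
  q <- dplyr::bind_rows(
    rdf_quads(g, n_iri, "rdf:type", iri("openbiodiv:ScientificName")),
    rdf_quads(g, n_iri, "rdfs:label", lit(label)),
    rdf_quads(g, n_iri, "dwc:verbatimTaxonRank", lit(rank))
  )
  if (!is.null(genus)) {
    q <- dplyr::bind_rows(q, rdf_quads(g, n_iri, "dwc:genus", lit(genus)))
  }
  if (!is.null(species)) {
    q <- dplyr::bind_rows(
      q, rdf_quads(g, n_iri, "dwc:specificEpithet", lit(species)))
  }
  if (!is.null(family)) {
    q <- dplyr::bind_rows(q, rdf_quads(g, n_iri, "dwc:family", lit(family)))
  }
  bm <- ctx$backbone_match
  if (!is.null(bm) && label %in% names(bm)) {
    q <- dplyr::bind_rows(
      q, rdf_quads(g, n_iri, "openbiodiv:hasGbifTaxon", iri(bm[[label]])))
  }
  list(doc = rdf_doc(q), iri = n_iri, label = label)
}

#' Construct a taxonomic name usage (TNU)
#'
#' A TNU reifies one mention of a scientific name at one position in the
#' document: a fresh resource per mention (usages are never deduplicated),
#' linked to the store-resolved name via `pkm:mentions`, contained in the
#' immediately enclosing part, and carrying a `dwciri:taxonomicStatus`
#' triple when the printed status maps to a status class.
#'
#' @inheritParams make_article
#' @return `list(doc, iri)`.
#' @export
make_tnu <- function(atoms, ctx, store) {
  name <- make_scientific_name(atoms, ctx, store)
  t_iri <- mint_structural(store, "tnu", ctx)
  g <- ctx$graph_iri
  q <- dplyr::bind_rows(
    rdf_quads(g, t_iri, "rdf:type", iri("openbiodiv:TaxonomicNameUsage")),
    rdf_quads(g, t_iri, "pkm:mentions", iri(name$iri))
  )
  parent <- parent_iri_of(ctx)
  if (!is.null(parent)) {
    q <- dplyr::bind_rows(q, contain_quads(g, parent, t_iri))
  }
  status <- atom1(atoms, "status")
  sm <- ctx$status_mapping
  if (!is.null(status) && !is.null(sm) && status %in% names(sm)) {
    q <- dplyr::bind_rows(
      q, rdf_quads(g, t_iri, "dwciri:taxonomicStatus", iri(sm[[status]])))
  }
  list(doc = rdf_add(name$doc, q), iri = t_iri)
}

#' Construct a materials-examined section with its occurrence records
#'
#' Emits the `openbiodiv:MaterialsExamined` section and, when the
#' corresponding fields are present, companion `dwc:Occurrence`
#' (recordedBy, typeStatus), `dwc:Event` (eventDate), location
#' (`dwc:Location` and `dcterms:Location`) and `dwc:Identification`
#' resources linked from the section via `dwc:occurrenceID`,
#' `dwc:eventID`, `dwc:locationID` and `dwc:identificationID`. A
#' holotype type status additionally yields an
#' `openbiodiv:HolotypeDescription` node contained in the section.
#'
#' @inheritParams make_article
#' @return `list(doc, iri)`.
#' @export
make_materials <- function(atoms, ctx, store) {
  m_iri <- mint_structural(store, "materials", ctx)
  g <- ctx$graph_iri
  q <- rdf_quads(g, m_iri, "rdf:type", iri("openbiodiv:MaterialsExamined"))
  parent <- parent_iri_of(ctx)
  if (!is.null(parent)) {
    q <- dplyr::bind_rows(q, contain_quads(g, parent, m_iri))
  }
  recorded <- atom_all(atoms, "recorded_by")
  type_status <- atom_all(atoms, "type_status")
  if (length(recorded) > 0L || length(type_status) > 0L) {
    o_iri <- get_or_mint(store, "occurrence", paste0(ctx$node_key, "#occ"))
    q <- dplyr::bind_rows(
      q,
      rdf_quads(g, o_iri, "rdf:type", iri("dwc:Occurrence")),
      rdf_quads(g, m_iri, "dwc:occurrenceID", iri(o_iri))
    )
    for (r in recorded) {
      q <- dplyr::bind_rows(
        q, rdf_quads(g, o_iri, "dwc:recordedBy", lit(r)))
    }
    for (ts in type_status) {
      q <- dplyr::bind_rows(
        q, rdf_quads(g, o_iri, "dwc:typeStatus", lit(ts)))
    }
  }
  event_date <- atom1(atoms, "event_date")
  if (!is.null(event_date)) {
    e_iri <- get_or_mint(store, "event", paste0(ctx$node_key, "#event"))
    date_obj <- if (grepl("^\\d{4}-\\d{2}-\\d{2}$", event_date)) {
      lit(event_date, datatype = "xsd:date")
    } else {
      lit(event_date)
    }
    q <- dplyr::bind_rows(
      q,
      rdf_quads(g, e_iri, "rdf:type", iri("dwc:Event")),
      rdf_quads(g, e_iri, "dwc:eventDate", date_obj),
      rdf_quads(g, m_iri, "dwc:eventID", iri(e_iri))
    )
  }
  locality <- atom1(atoms, "locality")
  if (!is.null(locality)) {
    l_iri <- get_or_mint(store, "location", paste0(ctx$node_key, "#loc"))
    q <- dplyr::bind_rows(
      q,
      rdf_quads(g, l_iri, "rdf:type", iri("dwc:Location")),
      rdf_quads(g, l_iri, "rdf:type", iri("dcterms:Location")),
      rdf_quads(g, l_iri, "dwc:verbatimLocality", lit(locality)),
      rdf_quads(g, m_iri, "dwc:locationID", iri(l_iri))
    )
  }
  identified_by <- atom1(atoms, "identified_by")
  if (!is.null(identified_by)) {
    i_iri <- get_or_mint(store, "identification",
                         paste0(ctx$node_key, "#ident"))
    q <- dplyr::bind_rows(
      q,
      rdf_quads(g, i_iri, "rdf:type", iri("dwc:Identification")),
      rdf_quads(g, i_iri, "dwc:identifiedBy", lit(identified_by)),
      rdf_quads(g, m_iri, "dwc:identificationID", iri(i_iri))
    )
  }
  if (any(tolower(type_status) == "holotype")) {
    h_iri <- get_or_mint(store, "holotype_description",
                         paste0(ctx$node_key, "#holotype"))
    q <- dplyr::bind_rows(
      q,
      rdf_quads(g, h_iri, "rdf:type", iri("openbiodiv:HolotypeDescription")),
      contain_quads(g, m_iri, h_iri)
    )
  }
  list(doc = rdf_doc(q), iri = m_iri)
}

#' Construct an institution resource
#'
#' The institution is typed `openbiodiv:Institution` (additionally
#' `openbiodiv:GRSciCollInstitution` when a collection-registry
#' identifier is present, in which case the registry IRI itself becomes
#' the resource IRI). Codes and the name are also asserted on the
#' enclosing treatment, which links to the institution via
#' `dwc:institutionID`.
#'
#' @inheritParams make_article
#' @return `list(doc, iri)`.
#' @export
make_institution <- function(atoms, ctx, store) {
  name <- atom1(atoms, "name")
  code <- atom1(atoms, "code")
  collection_code <- atom1(atoms, "collection_code")
  registry_id <- atom1(atoms, "registry_id")
  if (is.null(name) && is.null(code)) {
    stop("institution node carries neither a name nor a code",
         call. = FALSE)
  }
  label <- name %||% code
  g <- ctx$graph_iri
  if (!is.null(registry_id)) {
    i_iri <- registry_id
    id_store_put(store, "institution", label, i_iri)
  } else {
    i_iri <- get_or_mint(store, "institution", label)
  }
  q <- rdf_quads(g, i_iri, "rdf:type", iri("openbiodiv:Institution"))
  if (!is.null(registry_id)) {
    q <- dplyr::bind_rows(
      q, rdf_quads(g, i_iri, "rdf:type",
                   iri("openbiodiv:GRSciCollInstitution")))
  }
  if (!is.null(name)) {
    q <- dplyr::bind_rows(
      q,
      rdf_quads(g, i_iri, "openbiodiv:institutionName", lit(name)),
      rdf_quads(g, i_iri, "rdfs:label", lit(name))
    )
  }
  treatment <- nearest_ancestor(ctx, "treatment")
  if (!is.null(treatment)) {
    q <- dplyr::bind_rows(
      q, rdf_quads(g, treatment, "dwc:institutionID", iri(i_iri)))
    if (!is.null(name)) {
      q <- dplyr::bind_rows(
        q, rdf_quads(g, treatment, "openbiodiv:institutionName", lit(name)))
    }
    if (!is.null(code)) {
      q <- dplyr::bind_rows(
        q, rdf_quads(g, treatment, "dwc:institutionCode", lit(code)))
    }
    if (!is.null(collection_code)) {
      q <- dplyr::bind_rows(
        q, rdf_quads(g, treatment, "dwc:collectionCode",
                     lit(collection_code)))
    }
  }
  list(doc = rdf_doc(q), iri = i_iri)
}

external_id_schemes <- c("genbank", "boldsystems", "orcid", "zoobank",
                         "zenodo", "gbif")

#' Construct an external-identifier resource
#'
#' Links to genomic and registry databases: GenBank accessions, BOLD
#' identifiers, ORCID, ZooBank, Zenodo and GBIF ids. The identifier is
#' typed `datacite:ResourceIdentifier` (`datacite:PersonalIdentifier` for
#' ORCID), labelled with the raw identifier string and linked to its
#' scheme via `datacite:usesIdentifierScheme`; the containing section
#' points at it via `openbiodiv:mentionsIdentifier`.
#'
#' @inheritParams make_article
#' @return `list(doc, iri)`; `iri` is NULL when the identifier string is
#'   empty (skipped with a warning).
#' @export
make_external_identifier <- function(atoms, ctx, store) {
  scheme <- atom1(atoms, "scheme")
  value <- atom1(atoms, "value")
  if (is.null(scheme) || !scheme %in% external_id_schemes) {
    stop("unknown external identifier scheme '",
         scheme %||% "<missing>", "'", call. = FALSE)
  }
  if (is.null(value)) {
    warning("empty ", scheme, " identifier skipped", call. = FALSE)
    return(list(doc = rdf_doc(), iri = NULL))
  }
  g <- ctx$graph_iri
  if (scheme == "orcid") {
    e_iri <- paste0("https://orcid.org/",
                    sub("^https?://orcid\\.org/", "", value))
    id_store_put(store, "external_identifier", paste0(scheme, ":", value),
                 e_iri)
    type_class <- "datacite:PersonalIdentifier"
  } else {
    e_iri <- get_or_mint(store, "external_identifier",
                         paste0(scheme, ":", value))
    type_class <- "datacite:ResourceIdentifier"
  }
  q <- dplyr::bind_rows(
    rdf_quads(g, e_iri, "rdf:type", iri(type_class)),
    rdf_quads(g, e_iri, "rdfs:label", lit(value)),
    rdf_quads(g, e_iri, "datacite:usesIdentifierScheme",
              iri(paste0("datacite:", scheme)))
  )
  parent <- parent_iri_of(ctx)
  if (!is.null(parent)) {
    q <- dplyr::bind_rows(
      q, rdf_quads(g, parent, "openbiodiv:mentionsIdentifier", iri(e_iri)))
  }
  list(doc = rdf_doc(q), iri = e_iri)
}

# Dispatch table used by the extraction engine; schema files refer to
# constructors by these names.
constructor_registry <- function() {
  list(
    article = function(atoms, ctx, store, spec) make_article(atoms, ctx, store),
    person = function(atoms, ctx, store, spec) make_person(atoms, ctx, store),
    section = function(atoms, ctx, store, spec) {
      make_section(atoms, ctx, store, kind = spec$kind)
    },
    tnu = function(atoms, ctx, store, spec) make_tnu(atoms, ctx, store),
    materials = function(atoms, ctx, store, spec) make_materials(atoms, ctx, store),
    institution = function(atoms, ctx, store, spec) make_institution(atoms, ctx, store),
    external_identifier = function(atoms, ctx, store, spec) {
      make_external_identifier(atoms, ctx, store)
    }
  )
}
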