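# Deterministic generators of TaxPub / TaxonX articles and backbone TSVs
# with closed-form ground truth, plus the printed worked examples shipped
# as golden files. Names are synthetic Latin-like binomials built from
# syllable tables so no real taxon name carries unintended semantics.

syllables <- c("za", "re", "mi", "to", "lu", "ca", "ve", "ni", "so",
               "pa", "ke", "du", "ra", "fo", "bi", "ta", "mo", "li")

cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

gen_word <- function(n_syll) {
  paste(sample(syllables, n_syll, replace = TRUE), collapse = "")
}

gen_distinct_words <- function(n, n_syll, capitalize = FALSE) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    w <- gen_word(n_syll)
    if (capitalize) w <- cap1(w)
    if (!w %in% out) out <- c(out, w)
    guard <- guard + 1L
    if (guard > 10000L) stop("name pool exhausted", call. = FALSE)
  }
  out
}

xml_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Configuration for a synthetic article fixture
#'
#' The defaults describe a small but fully featured taxonomic article:
#' three authors, two treatments each with a nomenclature section citing
#' one earlier name, a materials-examined section with a holotype in the
#' first treatment, one institution with a collection-registry id, one
#' GenBank accession, and two figures.
#'
#' @param seed Integer seed; the same seed reproduces the same bytes.
#' @param n_authors,n_treatments,n_names,n_figures Counts.
#' @param statuses Named character vector mapping name-pool indices (as
#'   character) to printed status strings (e.g. `c("1" = "sp. nov.")`).
#' @param n_citations_per_nomenclature Citations in each nomenclature
#'   citations list; must be smaller than `n_names`.
#' @param institutions List of lists with `name`, `code`,
#'   `collection_code`, optional `registry_id`.
#' @param genomic_ids List of lists with `scheme`, `value` (attached to
#'   the first treatment's materials).
#' @param author_seed Separate seed for the author name pool; articles
#'   generated with the same `author_seed` share their authors (NULL:
#'   derived from `seed`, so pools differ between seeds).
#' @param share_affiliations All authors share one affiliation.
#' @param include_materials Emit materials-examined sections.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L,
                           n_authors = 3L,
                           n_treatments = 2L,
                           n_names = 6L,
                           n_figures = 2L,
                           statuses = c("1" = "sp. nov."),
                           n_citations_per_nomenclature = 1L,
                           institutions = list(list(
                             name = "Museu Nacional de Rio de Janeiro (MNRJ)",
                             code = "MNRJ",
                             collection_code = "MNRJ-ENT",
                             registry_id = "http://grbio.org/cool/zi1i-a0b5")),
                           genomic_ids = list(list(
                             scheme = "genbank", value = "MG779236")),
                           author_seed = NULL,
                           share_affiliations = FALSE,
                           include_materials = TRUE) {
  cfg <- list(
    seed = as.integer(seed), n_authors = as.integer(n_authors),
    n_treatments = as.integer(n_treatments),
    n_names = as.integer(n_names), n_figures = as.integer(n_figures),
    statuses = statuses,
    n_citations_per_nomenclature = as.integer(n_citations_per_nomenclature),
    institutions = institutions, genomic_ids = genomic_ids,
    author_seed = if (is.null(author_seed)) NULL else as.integer(author_seed),
    share_affiliations = isTRUE(share_affiliations),
    include_materials = isTRUE(include_materials)
  )
  stopifnot(cfg$n_names >= 1L, cfg$n_authors >= 0L, cfg$n_treatments >= 0L,
            cfg$n_figures >= 0L, cfg$n_citations_per_nomenclature >= 0L)
  if (cfg$n_citations_per_nomenclature >= cfg$n_names) {
    stop("n_citations_per_nomenclature must be smaller than n_names ",
         "(citations must cite names other than the treated one)",
         call. = FALSE)
  }
  if (cfg$n_citations_per_nomenclature > 0L && cfg$n_treatments == 0L) {
    stop("nomenclature citations require at least one treatment",
         call. = FALSE)
  }
  class(cfg) <- "fixture_config"
  cfg
}

# Index arithmetic shared by the generators and the ground truth:
# which name-pool index is used where.
treat_name_idx <- function(t, n) ((t - 1L) %% n) + 1L

status_of <- function(cfg, idx) {
  if (length(cfg$statuses) == 0L) return(NA_character_)
  unname(cfg$statuses[as.character(idx)])
}
cited_name_idx <- function(t, i, n) ((t - 1L + i) %% n) + 1L
figure_name_idx <- function(f, n) ((f - 1L) %% n) + 1L

fixture_materialize <- function(cfg) {
  ap_seed <- cfg$author_seed %||% (cfg$seed * 1009L + 7L)
  authors <- withr::with_seed(ap_seed, {
    # fixed-size pool so the first k authors coincide for any n_authors
    pool_n <- max(cfg$n_authors, 8L)
    given <- gen_distinct_words(pool_n, 2L, capitalize = TRUE)
    family <- gen_distinct_words(pool_n, 3L, capitalize = TRUE)
    if (cfg$n_authors > 0L) {
      purrr::map(seq_len(cfg$n_authors), function(i) {
        list(
          given = given[[i]], surname = family[[i]],
          orcid = if (i == 1L) {
            sprintf("https://orcid.org/0000-000%d-%04d-%04d",
                    sample(1:9, 1), sample(0:9999, 1), sample(0:9999, 1))
          },
          aff_idx = if (cfg$share_affiliations) 1L else i
        )
      })
    } else {
      list()
    }
  })
  withr::with_seed(cfg$seed, {
    genera <- gen_distinct_words(cfg$n_names, 3L, capitalize = TRUE)
    epithets <- gen_distinct_words(cfg$n_names, 3L)
    name_labels <- paste(genera, epithets)
    n_affs <- if (cfg$n_authors == 0L) 0L else
      if (cfg$share_affiliations) 1L else cfg$n_authors
    affs <- if (n_affs > 0L) {
      paste0("Institute of ", gen_distinct_words(n_affs, 4L, TRUE),
             ", ", gen_distinct_words(n_affs, 3L, TRUE))
    } else {
      character(0)
    }
    doi <- sprintf("10.3897/synth.%d.e%04d", cfg$seed, sample(0:9999, 1))
    pub_date <- sprintf("%04d-%02d-%02d", 2000L + sample(0:20, 1),
                        sample(1:12, 1), sample(1:28, 1))
    list(genera = genera, epithets = epithets, name_labels = name_labels,
         authors = authors, affs = affs, doi = doi, pub_date = pub_date,
         title = paste("A revision of", genera[[1]],
                       "with new records"),
         publisher = "Pensoft Publishers",
         collector = paste(gen_distinct_words(1L, 2L, TRUE),
                           gen_distinct_words(1L, 3L, TRUE)),
         identifier_person = paste(gen_distinct_words(1L, 2L, TRUE),
                                   gen_distinct_words(1L, 3L, TRUE)),
         locality = paste0("Near ", gen_distinct_words(1L, 3L, TRUE)),
         event_date = sprintf("%04d-%02d-%02d", 1990L + sample(0:25, 1),
                              sample(1:12, 1), sample(1:28, 1)))
  })
}

#' Closed-form ground truth for a fixture
#'
#' Expected per-type resource counts, distinct-name census and expected
#' update-rule edges, computed from the configuration by arithmetic alone
#' (never by running the conversion pipeline).
#'
#' @param cfg A [fixture_config()].
#' @param dialect `"taxpub"` or `"taxonx"`.
#' @return List with `type_counts` (named integer vector keyed by class
#'   CURIE), `name_labels`, `replacement_edges`, `related_edges`.
#' @export
fixture_ground_truth <- function(cfg, dialect = c("taxpub", "taxonx")) {
  dialect <- match.arg(dialect)
  mat <- fixture_materialize(cfg)
  n <- cfg$n_names
  T_ <- cfg$n_treatments
  cc <- cfg$n_citations_per_nomenclature
  status_map <- default_status_mapping()
  used_idx <- integer(0)
  # abstract
  used_idx <- c(used_idx, 1L)
  if (dialect == "taxpub") {
    used_idx <- c(used_idx, treat_name_idx(2L, n), treat_name_idx(3L, n))
  }
  tnu_count <- if (dialect == "taxpub") 3L else 1L
  for (t in seq_len(T_)) {
    used_idx <- c(used_idx, treat_name_idx(t, n))
    tnu_count <- tnu_count + 1L + cc
    if (dialect == "taxonx") {
      tnu_count <- tnu_count + 1L  # per-treatment discussion usage
      used_idx <- c(used_idx, treat_name_idx(t, n))
    }
    for (i in seq_len(cc)) {
      used_idx <- c(used_idx, cited_name_idx(t, i, n))
    }
  }
  for (f in seq_len(cfg$n_figures)) {
    used_idx <- c(used_idx, figure_name_idx(f, n))
    tnu_count <- tnu_count + 1L
  }
  used_idx <- sort(unique(used_idx))
  n_inst <- length(cfg$institutions)
  n_gen <- length(cfg$genomic_ids)
  holotype_treatments <- if (cfg$include_materials && T_ >= 1L) 1L else 0L
  mat_T <- if (cfg$include_materials) T_ else 0L
  type_counts <- c(
    "fabio:JournalArticle" = 1L,
    "foaf:Person" = cfg$n_authors,
    "doco:Title" = 1L,
    "sro:Abstract" = 1L,
    "openbiodiv:KeywordGroup" = if (dialect == "taxpub") 1L else 0L,
    "deo:Introduction" = if (dialect == "taxpub") 1L else 0L,
    "orb:Discussion" = if (dialect == "taxpub") 1L else T_,
    "openbiodiv:Treatment" = T_,
    "openbiodiv:NomenclatureSection" = T_,
    "openbiodiv:NomenclatureCitationsList" = if (cc > 0L) T_ else 0L,
    "deo:BibliographicReference" =
      T_ * cc + if (dialect == "taxpub") 2L else 0L,
    "doco:BibliographicReferenceList" = if (dialect == "taxpub") 1L else 0L,
    "openbiodiv:MaterialsExamined" = mat_T,
    "dwc:Occurrence" = mat_T,
    "dwc:Event" = mat_T,
    "dwc:Location" = mat_T,
    "dwc:Identification" = mat_T,
    "openbiodiv:HolotypeDescription" = holotype_treatments,
    "openbiodiv:DiagnosisSection" = T_,
    "openbiodiv:DistributionSection" = T_,
    "openbiodiv:TaxonomicKey" = T_,
    "doco:Figure" = cfg$n_figures,
    "openbiodiv:TaxonomicNameUsage" = tnu_count,
    "openbiodiv:ScientificName" = length(used_idx),
    "openbiodiv:Institution" = if (mat_T > 0L) min(n_inst, 1000L) else 0L,
    "datacite:ResourceIdentifier" =
      if (mat_T > 0L && T_ >= 1L) n_gen else 0L
  )
  # update-rule edges at label level
  repl <- list()
  rel <- list()
  repl_class <- expand_curie("openbiodiv:ReplacementName")
  for (t in seq_len(T_)) {
    idx <- treat_name_idx(t, n)
    status <- status_of(cfg, idx)
    cited <- vapply(seq_len(cc), function(i) cited_name_idx(t, i, n),
                    integer(1))
    if (!is.na(status) && status %in% names(status_map) &&
        status_map[[status]] == repl_class) {
      for (ci in cited) {
        repl[[length(repl) + 1L]] <-
          c(from = mat$name_labels[[ci]], to = mat$name_labels[[idx]])
      }
    }
    sec_names <- unique(c(idx, cited))
    for (a in sec_names) for (b in sec_names) {
      if (a != b) {
        rel[[length(rel) + 1L]] <-
          c(from = mat$name_labels[[a]], to = mat$name_labels[[b]])
      }
    }
  }
  edge_tbl <- function(lst) {
    if (length(lst) == 0L) {
      return(tibble::tibble(from = character(0), to = character(0)))
    }
    dplyr::distinct(tibble::tibble(
      from = vapply(lst, `[[`, character(1), "from"),
      to = vapply(lst, `[[`, character(1), "to")))
  }
  list(
    type_counts = type_counts,
    name_labels = mat$name_labels[used_idx],
    replacement_edges = edge_tbl(repl),
    related_edges = edge_tbl(rel),
    families = stats::setNames(fixture_family_of(mat$genera),
                               mat$name_labels),
    doi = mat$doi,
    pub_date = mat$pub_date,
    collector = mat$collector,
    event_date = mat$event_date,
    author_labels = vapply(mat$authors, function(a) {
      paste(a$given, a$surname)
    }, character(1))
  )
}

taxpub_name_xml <- function(genus, epithet, family = NULL) {
  fam_part <- if (!is.null(family)) {
    paste0("<tp:taxon-name-part taxon-name-part-type=\"family\" reg=\"",
           xml_esc(family), "\">", xml_esc(family), "</tp:taxon-name-part>")
  } else {
    ""
  }
  paste0(
    "<tp:taxon-name>", fam_part,
    "<tp:taxon-name-part taxon-name-part-type=\"genus\" reg=\"",
    xml_esc(genus), "\">", xml_esc(genus), "</tp:taxon-name-part>",
    "<tp:taxon-name-part taxon-name-part-type=\"species\" reg=\"",
    xml_esc(epithet), "\">", xml_esc(epithet), "</tp:taxon-name-part>",
    "</tp:taxon-name>")
}

taxonx_name_xml <- function(genus, epithet, family = NULL) {
  fam_part <- if (!is.null(family)) {
    paste0("<dwc:Family>", xml_esc(family), "</dwc:Family>")
  } else {
    ""
  }
  paste0("<tax:name>", fam_part, "<dwc:Genus>", xml_esc(genus),
         "</dwc:Genus>",
         "<dwc:Species>", xml_esc(epithet), "</dwc:Species></tax:name>")
}

fixture_family_of <- function(genus) paste0(genus, "idae")

materials_inner_xml <- function(cfg, mat, t) {
  parts <- character(0)
  if (t == 1L) {
    parts <- c(parts, paste0(
      "<named-content content-type=\"dwc:typeStatus\">holotype",
      "</named-content>"))
  }
  parts <- c(parts,
    paste0("<named-content content-type=\"dwc:recordedBy\">",
           xml_esc(mat$collector), "</named-content>"),
    paste0("<named-content content-type=\"dwc:eventDate\">",
           mat$event_date, "</named-content>"),
    paste0("<named-content content-type=\"dwc:verbatimLocality\">",
           xml_esc(mat$locality), "</named-content>"),
    paste0("<named-content content-type=\"dwc:identifiedBy\">",
           xml_esc(mat$identifier_person), "</named-content>"))
  for (k in seq_along(cfg$institutions)) {
    inst <- cfg$institutions[[k]]
    target_t <- ((k - 1L) %% cfg$n_treatments) + 1L
    if (target_t != t) next
    attrs <- paste0(" code=\"", xml_esc(inst$code), "\"")
    if (!is.null(inst$collection_code)) {
      attrs <- paste0(attrs, " collection-code=\"",
                      xml_esc(inst$collection_code), "\"")
    }
    if (!is.null(inst$registry_id)) {
      attrs <- paste0(attrs, " grscicoll-id=\"",
                      xml_esc(inst$registry_id), "\"")
    }
    parts <- c(parts, paste0(
      "<institution", attrs, "><institution-name>",
      xml_esc(inst$name), "</institution-name></institution>"))
  }
  if (t == 1L) {
    for (gid in cfg$genomic_ids) {
      parts <- c(parts, paste0(
        "<ext-link ext-link-type=\"", gid$scheme, "\">",
        xml_esc(gid$value), "</ext-link>"))
    }
  }
  paste0("<p>", paste(parts, collapse = ""), "</p>")
}

#' Generate a synthetic TaxPub article
#'
#' Produces a well-formed TaxPub document whose every element is
#' reachable by the shipped TaxPub schema, together with its closed-form
#' ground truth. Byte-identical output for the same configuration.
#'
#' @param cfg A [fixture_config()].
#' @return List: `xml` (string), `truth` (see [fixture_ground_truth()]),
#'   `config`.
#' @export
gen_taxpub <- function(cfg = fixture_config()) {
  mat <- fixture_materialize(cfg)
  n <- cfg$n_names
  name_xml <- function(i) taxpub_name_xml(mat$genera[[i]],
                                          mat$epithets[[i]])
  authors_xml <- character(0)
  for (k in seq_along(mat$authors)) {
    a <- mat$authors[[k]]
    orcid_xml <- if (!is.null(a$orcid)) {
      paste0("<uri content-type=\"orcid\">", a$orcid, "</uri>")
    } else {
      ""
    }
    authors_xml <- c(authors_xml, paste0(
      "<contrib contrib-type=\"author\"><name>",
      "<surname>", xml_esc(a$surname), "</surname>",
      "<given-names>", xml_esc(a$given), "</given-names></name>",
      orcid_xml,
      "<xref ref-type=\"aff\" rid=\"", a$aff_idx, "\">", a$aff_idx,
      "</xref></contrib>"))
  }
  affs_xml <- character(0)
  n_affs <- length(mat$affs)
  for (k in seq_len(n_affs)) {
    # the id carries an "A" prefix while the rid does not: the documented
    # cross-reference mismatch the matching cascade must absorb
    affs_xml <- c(affs_xml, paste0(
      "<aff id=\"A", k, "\"><label>", k, "</label><addr-line>",
      xml_esc(mat$affs[[k]]), "</addr-line></aff>"))
  }
  treatments_xml <- character(0)
  for (t in seq_len(cfg$n_treatments)) {
    idx <- treat_name_idx(t, n)
    status <- status_of(cfg, idx)
    status_xml <- if (!is.na(status)) {
      paste0("<tp:taxon-status>", xml_esc(status), "</tp:taxon-status>")
    } else {
      ""
    }
    cites <- character(0)
    for (i in seq_len(cfg$n_citations_per_nomenclature)) {
      ci <- cited_name_idx(t, i, n)
      cites <- c(cites, paste0("<tp:nomenclature-citation>",
                               name_xml(ci), "</tp:nomenclature-citation>"))
    }
    cit_list <- if (length(cites) > 0L) {
      paste0("<tp:nomenclature-citation-list>",
             paste(cites, collapse = ""), "</tp:nomenclature-citation-list>")
    } else {
      ""
    }
    materials <- if (cfg$include_materials) {
      paste0("<tp:treatment-sec sec-type=\"materials_examined\">",
             materials_inner_xml(cfg, mat, t), "</tp:treatment-sec>")
    } else {
      ""
    }
    nom_name <- taxpub_name_xml(mat$genera[[idx]], mat$epithets[[idx]],
                                fixture_family_of(mat$genera[[idx]]))
    treatments_xml <- c(treatments_xml, paste0(
      "<tp:taxon-treatment>",
      "<tp:nomenclature>", nom_name, status_xml, cit_list,
      "</tp:nomenclature>",
      materials,
      "<tp:treatment-sec sec-type=\"diagnosis\"><p>Distinct.</p>",
      "</tp:treatment-sec>",
      "<tp:treatment-sec sec-type=\"distribution\"><p>Widespread.</p>",
      "</tp:treatment-sec>",
      "<tp:treatment-sec sec-type=\"key\"><p>1. Key couplet.</p>",
      "</tp:treatment-sec>",
      "</tp:taxon-treatment>"))
  }
  figures_xml <- character(0)
  for (f in seq_len(cfg$n_figures)) {
    fi <- figure_name_idx(f, n)
    figures_xml <- c(figures_xml, paste0(
      "<fig id=\"F", f, "\"><caption><p>Habitus of ", name_xml(fi),
      "</p></caption></fig>"))
  }
  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<article xmlns:tp=\"http://www.plazi.org/taxpub\">",
    "<front>",
    "<journal-meta><publisher><publisher-name>",
    xml_esc(mat$publisher),
    "</publisher-name></publisher></journal-meta>",
    "<article-meta>",
    "<article-id pub-id-type=\"doi\">", mat$doi, "</article-id>",
    "<title-group><article-title>", xml_esc(mat$title),
    "</article-title></title-group>",
    "<contrib-group>", paste(authors_xml, collapse = ""),
    "</contrib-group>",
    paste(affs_xml, collapse = ""),
    "<pub-date iso-8601-date=\"", mat$pub_date, "\"/>",
    "<abstract><p>We revise ", name_xml(1L), " and allies.</p></abstract>",
    "<kwd-group><kwd>taxonomy</kwd><kwd>biodiversity</kwd></kwd-group>",
    "</article-meta>",
    "</front>",
    "<body>",
    "<sec sec-type=\"introduction\"><title>Introduction</title><p>",
    "The genus includes ", name_xml(treat_name_idx(2L, n)),
    ".</p></sec>",
    paste(treatments_xml, collapse = ""),
    paste(figures_xml, collapse = ""),
    "<sec sec-type=\"discussion\"><title>Discussion</title><p>",
    "Compare ", name_xml(treat_name_idx(3L, n)), ".</p></sec>",
    "</body>",
    "<back><ref-list>",
    "<ref id=\"B1\"><mixed-citation>Author A (1900) On beetles.",
    "</mixed-citation></ref>",
    "<ref id=\"B2\"><mixed-citation>Author B (1950) More beetles.",
    "</mixed-citation></ref>",
    "</ref-list></back>",
    "</article>\n")
  list(xml = xml, truth = fixture_ground_truth(cfg, "taxpub"),
       config = cfg)
}

#' Generate a synthetic TaxonX treatment document
#'
#' As [gen_taxpub()], but in the TaxonX dialect: no keyword group, no
#' introduction and no bibliographic reference list are emitted, and the
#' discussion lives inside each treatment.
#'
#' @param cfg A [fixture_config()].
#' @return List: `xml`, `truth`, `config`.
#' @export
gen_taxonx <- function(cfg = fixture_config()) {
  mat <- fixture_materialize(cfg)
  n <- cfg$n_names
  name_xml <- function(i) taxonx_name_xml(mat$genera[[i]],
                                          mat$epithets[[i]])
  authors_xml <- character(0)
  for (a in mat$authors) {
    orcid_xml <- if (!is.null(a$orcid)) {
      paste0("<mods:nameIdentifier type=\"orcid\">", a$orcid,
             "</mods:nameIdentifier>")
    } else {
      ""
    }
    authors_xml <- c(authors_xml, paste0(
      "<mods:name type=\"personal\">",
      "<mods:namePart type=\"given\">", xml_esc(a$given),
      "</mods:namePart>",
      "<mods:namePart type=\"family\">", xml_esc(a$surname),
      "</mods:namePart>", orcid_xml,
      "<mods:affiliation>", xml_esc(mat$affs[[a$aff_idx]]),
      "</mods:affiliation></mods:name>"))
  }
  treatments_xml <- character(0)
  for (t in seq_len(cfg$n_treatments)) {
    idx <- treat_name_idx(t, n)
    status <- status_of(cfg, idx)
    status_xml <- if (!is.na(status)) {
      paste0("<tax:status>", xml_esc(status), "</tax:status>")
    } else {
      ""
    }
    cites <- character(0)
    for (i in seq_len(cfg$n_citations_per_nomenclature)) {
      ci <- cited_name_idx(t, i, n)
      cites <- c(cites, paste0("<tax:ref>", name_xml(ci), "</tax:ref>"))
    }
    cit_list <- if (length(cites) > 0L) {
      paste0("<tax:ref_group>", paste(cites, collapse = ""),
             "</tax:ref_group>")
    } else {
      ""
    }
    materials <- if (cfg$include_materials) {
      paste0("<tax:div type=\"materials_examined\">",
             materials_inner_xml(cfg, mat, t), "</tax:div>")
    } else {
      ""
    }
    nom_name <- taxonx_name_xml(mat$genera[[idx]], mat$epithets[[idx]],
                                fixture_family_of(mat$genera[[idx]]))
    treatments_xml <- c(treatments_xml, paste0(
      "<tax:treatment>",
      "<tax:nomenclature>", nom_name, status_xml, cit_list,
      "</tax:nomenclature>",
      materials,
      "<tax:div type=\"diagnosis\"><p>Distinct.</p></tax:div>",
      "<tax:div type=\"distribution\"><p>Widespread.</p></tax:div>",
      "<tax:div type=\"key\"><p>1. Key couplet.</p></tax:div>",
      "<tax:div type=\"discussion\"><p>Discussion of ", name_xml(idx),
      "</p></tax:div>",
      "</tax:treatment>"))
  }
  figures_xml <- character(0)
  for (f in seq_len(cfg$n_figures)) {
    fi <- figure_name_idx(f, n)
    figures_xml <- c(figures_xml, paste0(
      "<tax:figure><tax:caption>Habitus of ", name_xml(fi),
      "</tax:caption></tax:figure>"))
  }
  xml <- paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<tax:taxonx xmlns:tax=\"http://www.taxonx.org/schema/v1\" ",
    "xmlns:mods=\"http://www.loc.gov/mods/v3\" ",
    "xmlns:dwc=\"http://digir.net/schema/conceptual/darwin/2003/1.0\">",
    "<tax:taxonxHeader><mods:mods>",
    "<mods:titleInfo><mods:title>", xml_esc(mat$title),
    "</mods:title></mods:titleInfo>",
    paste(authors_xml, collapse = ""),
    "<mods:identifier type=\"DOI\">", mat$doi, "</mods:identifier>",
    "<mods:originInfo><mods:dateIssued>", mat$pub_date,
    "</mods:dateIssued><mods:publisher>", xml_esc(mat$publisher),
    "</mods:publisher></mods:originInfo>",
    "<mods:abstract>We revise ", name_xml(1L), " and allies.",
    "</mods:abstract>",
    "</mods:mods></tax:taxonxHeader>",
    "<tax:taxonxBody>",
    paste(treatments_xml, collapse = ""),
    paste(figures_xml, collapse = ""),
    "</tax:taxonxBody>",
    "</tax:taxonx>\n")
  list(xml = xml, truth = fixture_ground_truth(cfg, "taxonx"),
       config = cfg)
}

rank_ladder <- c("kingdom", "phylum", "class", "order", "family",
                 "genus", "species")

#' Generate a synthetic backbone-taxonomy TSV
#'
#' Builds a rank-consistent forest (ranks never invert along a
#' root-to-leaf path) of `n_taxa` accepted rows plus optional synonym
#' rows, as a Darwin Core TSV string, together with closed-form ground
#' truth (edge and concept counts, child sets per parent).
#'
#' @param n_taxa Number of accepted rows (>= 1).
#' @param max_depth Maximum tree depth (capped at the 7-rank ladder).
#' @param seed Integer seed.
#' @param n_synonyms Number of synonym rows appended.
#' @return List: `tsv` (string), `truth` (list with `n_accepted`,
#'   `n_edges`, `children` map, `rows` tibble).
#' @export
gen_backbone <- function(n_taxa, max_depth = 4L, seed = 1L,
                         n_synonyms = 0L) {
  stopifnot(n_taxa >= 1L)
  max_depth <- min(as.integer(max_depth), length(rank_ladder))
  withr::with_seed(seed, {
    words <- gen_distinct_words(n_taxa + n_synonyms, 3L,
                                capitalize = TRUE)
    epithets <- gen_distinct_words(n_taxa + n_synonyms, 3L)
    id <- seq_len(n_taxa) * 100L + sample(0:99, n_taxa, replace = TRUE)
    depth <- integer(n_taxa)
    parent <- rep(NA_integer_, n_taxa)
    depth[1L] <- 1L
    for (i in seq_len(n_taxa)[-1L]) {
      eligible <- which(depth[seq_len(i - 1L)] < max_depth)
      if (length(eligible) == 0L) eligible <- 1L
      p <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      parent[i] <- id[p]
      depth[i] <- depth[p] + 1L
    }
    rank <- rank_ladder[pmin(depth + (length(rank_ladder) - max_depth),
                             length(rank_ladder))]
    # use the tail of the ladder so max_depth chains end at species
    name <- character(n_taxa)
    genus_col <- rep(NA_character_, n_taxa)
    family_col <- rep(NA_character_, n_taxa)
    for (i in seq_len(n_taxa)) {
      if (rank[i] == "species") {
        pidx <- match(parent[i], id)
        gname <- if (!is.na(pidx) && rank[pidx] == "genus") {
          words[pidx]
        } else {
          words[i]
        }
        name[i] <- paste(gname, epithets[i])
        genus_col[i] <- gname
      } else {
        name[i] <- words[i]
        if (rank[i] == "genus") genus_col[i] <- words[i]
      }
      # nearest family ancestor
      cur <- parent[i]
      while (!is.na(cur)) {
        ci <- match(cur, id)
        if (rank[ci] == "family") { family_col[i] <- words[ci]; break }
        cur <- parent[ci]
      }
    }
    rows <- tibble::tibble(
      taxonID = id,
      parentNameUsageID = parent,
      acceptedNameUsageID = NA_integer_,
      canonicalName = name,
      scientificName = name,
      taxonRank = rank,
      taxonomicStatus = "accepted",
      genus = genus_col,
      family = family_col
    )
    if (n_synonyms > 0L) {
      syn_ids <- max(id) + seq_len(n_synonyms) * 7L
      syn <- tibble::tibble(
        taxonID = syn_ids,
        parentNameUsageID = NA_integer_,
        acceptedNameUsageID = id[sample(seq_len(n_taxa), n_synonyms,
                                        replace = TRUE)],
        canonicalName = paste(words[n_taxa + seq_len(n_synonyms)],
                              epithets[n_taxa + seq_len(n_synonyms)]),
        scientificName = NA_character_,
        taxonRank = "species",
        taxonomicStatus = "synonym",
        genus = NA_character_,
        family = NA_character_
      )
      syn$scientificName <- syn$canonicalName
      rows <- dplyr::bind_rows(rows, syn)
    }
    tsv <- readr::format_tsv(rows, na = "")
    children <- split(rows$taxonID[!is.na(rows$parentNameUsageID) &
                                     rows$taxonomicStatus == "accepted"],
                      rows$parentNameUsageID[
                        !is.na(rows$parentNameUsageID) &
                          rows$taxonomicStatus == "accepted"])
    list(
      tsv = tsv,
      truth = list(
        n_accepted = n_taxa,
        n_edges = sum(!is.na(parent)),
        children = children,
        rows = rows
      )
    )
  })
}

#' The printed worked examples as XML / golden-graph pairs
#'
#' Three reference conversions shipped as files: a marked-up taxonomic
#' name (with regularized parts differing from the displayed
#' abbreviation), an author with an ORCID and a cross-referenced
#' affiliation, and article metadata with an empty introduction. The
#' golden TriG files hold the corresponding reference triples. The name
#' fixture normalizes a typographic artefact of the source (a Cyrillic
#' character inside the closing tag) and keeps the abbreviated displayed
#' genus, which exercises regularized-part extraction.
#'
#' @return A list of entries with `id`, `xml_path`, `golden_path`,
#'   `xml` (string) and `golden` (a `triple_doc`).
#' @export
worked_examples <- function() {
  ids <- c("table2", "table4", "table5")
  purrr::map(ids, function(id) {
    xml_path <- system.file("extdata", "golden", paste0(id, ".xml"),
                            package = "taxograph", mustWork = TRUE)
    golden_path <- system.file("extdata", "golden", paste0(id, ".trig"),
                               package = "taxograph", mustWork = TRUE)
    list(
      id = id,
      xml_path = xml_path,
      golden_path = golden_path,
      xml = paste(readLines(xml_path, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n"),
      golden = read_trig(golden_path)
    )
  })
}

#' Convert one worked example with the package pipeline
#'
#' `table2` extracts the name fragment's atoms and constructs the
#' scientific name (with the backbone link configured for the printed
#' label); `table4` extracts the author with affiliation matching;
#' `table5` converts the minimal article document.
#'
#' @param id `"table2"`, `"table4"` or `"table5"`.
#' @param store An [id_store()].
#' @return A `triple_doc`.
#' @export
convert_worked_example <- function(id, store = id_store()) {
  ex <- purrr::detect(worked_examples(), ~ .x$id == id)
  if (is.null(ex)) stop("unknown worked example '", id, "'", call. = FALSE)
  schema <- load_schema("taxpub")
  ns <- schema_ns(schema)
  frag_graph <- "http://openbiodiv.net/Fragments"
  if (id == "table2") {
    node <- xml2::read_xml(ex$xml)
    atoms <- extract_atoms(node, schema$nodes$tnu, ns)
    ctx <- list(
      graph_iri = frag_graph,
      backbone_match = c("Zelus casii" = gbif_iri(
        "F1DD0CF0-217D-422B-BAA4-58901976D7B4", 9146644,
        "scientific_name"))
    )
    make_scientific_name(atoms, ctx, store)$doc
  } else if (id == "table4") {
    doc <- xml2::read_xml(ex$xml)
    node <- xml2::xml_find_first(
      doc, "//contrib[@contrib-type='author']")
    atoms <- extract_atoms(node, schema$nodes$person, ns)
    aff <- resolve_affiliations(node, doc)
    if (length(aff) > 0L) atoms$affiliation <- aff
    make_person(atoms, list(graph_iri = frag_graph), store)$doc
  } else {
    parse_article(ex$xml, schema = schema, store = store, quiet = TRUE)
  }
}
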