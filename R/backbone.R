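# Import of a Darwin Core backbone taxonomy (one row = one taxonomic
# concept) as RDF: concepts, scientific names, concept labels, a SKOS
# broader hierarchy and reified RCC-5 proper-part relations.

#' Read a Darwin Core backbone-taxonomy TSV
#'
#' Expects a header of Darwin Core column names including `taxonID`;
#' recognised columns are typed, unknown columns are preserved. Rows
#' whose `taxonID` does not parse as an integer are skipped with a
#' message naming the line.
#'
#' @param tsv Path to a TSV file or a literal TSV string.
#' @param quiet Suppress skipped-row messages.
#' @return A tibble of backbone rows.
#' @export
read_backbone <- function(tsv, quiet = FALSE) {
  raw <- readr::read_tsv(
    if (grepl("\t", tsv) || grepl("\n", tsv)) I(tsv) else tsv,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!"taxonID" %in% names(raw)) {
    stop("backbone TSV has no taxonID column", call. = FALSE)
  }
  ids <- suppressWarnings(as.integer(raw$taxonID))
  bad <- which(is.na(ids))
  if (length(bad) > 0L && !quiet) {
    message("skipping ", length(bad), " unparseable backbone row(s) at ",
            "line(s) ", paste(bad + 1L, collapse = ", "))
  }
  rows <- raw[!is.na(ids), , drop = FALSE]
  rows$taxonID <- ids[!is.na(ids)]
  for (col in c("parentNameUsageID", "acceptedNameUsageID")) {
    if (col %in% names(rows)) {
      rows[[col]] <- suppressWarnings(as.integer(rows[[col]]))
    } else {
      rows[[col]] <- NA_integer_
    }
  }
  for (col in c("scientificName", "canonicalName", "taxonRank",
                "taxonomicStatus", "genus", "family")) {
    if (!col %in% names(rows)) rows[[col]] <- NA_character_
  }
  tibble::as_tibble(rows)
}

backbone_name_label <- function(row) {
  lbl <- row$canonicalName
  if (is.na(lbl) || !nzchar(lbl)) lbl <- row$scientificName
  normalize_label(lbl)
}

is_accepted_status <- function(status) {
  !is.na(status) & tolower(status) %in%
    c("accepted", "doubtful", "valid")
}

#' RDF for one accepted backbone row
#'
#' Emits three resources sharing the version's base UUID: the taxonomic
#' concept (suffix = the row's taxonID), its scientific name (`-scName`)
#' and its concept label (`-label`, a literal of the form
#' `"<name> sec. <citation>"`). The concept links to the name through
#' both `openbiodiv:hasScientificName` and `openbiodiv:scientificName`
#' (both predicate spellings occur in published data) and to the version
#' resource.
#'
#' @param row One-row tibble from [read_backbone()].
#' @param version List with `base_uuid`, `citation`, `version_iri`,
#'   `graph_iri` (see [backbone_version()]).
#' @return A `triple_doc`.
#' @export
concept_graph <- function(row, version) {
  if (!is_accepted_status(row$taxonomicStatus)) {
    stop("concept_graph() requires an accepted row; got status '",
         row$taxonomicStatus, "' (synonyms are handled separately)",
         call. = FALSE)
  }
  g <- version$graph_iri
  concept <- gbif_iri(version$base_uuid, row$taxonID, "concept")
  name <- gbif_iri(version$base_uuid, row$taxonID, "scientific_name")
  label <- gbif_iri(version$base_uuid, row$taxonID, "concept_label")
  name_label <- backbone_name_label(row)
  q <- dplyr::bind_rows(
    rdf_quads(g, concept, "rdf:type", iri("openbiodiv:TaxonomicConcept")),
    rdf_quads(g, concept, "openbiodiv:hasScientificName", iri(name)),
    rdf_quads(g, concept, "openbiodiv:scientificName", iri(name)),
    rdf_quads(g, concept, "openbiodiv:hasTaxonomicConceptLabel", iri(label)),
    rdf_quads(g, concept, "dcterms:isPartOf", iri(version$version_iri)),
    rdf_quads(g, name, "rdf:type", iri("openbiodiv:ScientificName")),
    rdf_quads(g, name, "rdfs:label", lit(name_label)),
    rdf_quads(g, label, "rdf:type", iri("openbiodiv:TaxonomicConceptLabel")),
    rdf_quads(g, label, "rdfs:label",
              lit(paste0(name_label, " sec. ", version$citation)))
  )
  if (!is.na(row$taxonRank) && nzchar(row$taxonRank)) {
    q <- dplyr::bind_rows(
      q, rdf_quads(g, name, "dwc:taxonRank", lit(row$taxonRank)))
  }
  if (!is.na(row$genus) && nzchar(row$genus)) {
    q <- dplyr::bind_rows(
      q, rdf_quads(g, name, "dwc:genus", lit(row$genus)))
  }
  if (!is.na(row$family) && nzchar(row$family)) {
    q <- dplyr::bind_rows(
      q, rdf_quads(g, name, "dwc:family", lit(row$family)))
  }
  rdf_doc(q)
}

#' Describe one backbone import run
#'
#' All concepts of a run share the run's base UUID; the version resource
#' itself carries the citation.
#'
#' @param base_uuid UUID string; freshly random when NULL.
#' @param citation Bibliographic citation of the backbone version.
#' @return List with `base_uuid`, `citation`, `version_iri`, `graph_iri`.
#' @export
backbone_version <- function(citation, base_uuid = NULL) {
  if (is.null(base_uuid)) base_uuid <- random_uuid()
  version_iri <- paste0("http://openbiodiv.net/", base_uuid)
  list(base_uuid = base_uuid, citation = citation,
       version_iri = version_iri, graph_iri = version_iri)
}

rcc5_vocabulary <- function() {
  # Vocabulary local names follow the RCC-5 relation set; production
  # property names are configuration-overridable (see hierarchy_graph).
  c(
    EqualTo            = "openbiodiv:EqualTo_INT",
    ProperPart         = "openbiodiv:ProperPart_INT",
    InverseProperPart  = "openbiodiv:InverseProperPart_INT",
    PartialOverlap     = "openbiodiv:PartialOverlap_INT",
    Disjoint           = "openbiodiv:Disjoint_INT"
  )
}

#' SKOS hierarchy and reified RCC-5 relations for a backbone forest
#'
#' For every accepted child-parent pair the hierarchy is encoded twice:
#' directly as `child skos:broader parent`, and as a reified RCC-5
#' statement (the child's circumscription is a proper part of the
#' parent's). Dangling parent pointers produce a warning and no edge; a
#' cycle is an error.
#'
#' @param rows Tibble from [read_backbone()].
#' @param version A [backbone_version()].
#' @param rcc5_predicates Named list overriding the reification property
#'   IRIs (`subject`, `object`, `relation`).
#' @return A `triple_doc`.
#' @export
hierarchy_graph <- function(rows, version,
                            rcc5_predicates = list(
                              subject = "openbiodiv:rcc5Subject",
                              object = "openbiodiv:rcc5Object",
                              relation = "openbiodiv:rcc5Relation")) {
  acc <- rows[is_accepted_status(rows$taxonomicStatus), , drop = FALSE]
  g <- version$graph_iri
  # cycle detection over parent pointers
  parent_of <- stats::setNames(acc$parentNameUsageID, acc$taxonID)
  for (start in acc$taxonID) {
    seen <- integer(0)
    cur <- start
    while (!is.na(cur)) {
      if (cur %in% seen) {
        stop("cycle detected in backbone parent pointers at taxonID ",
             cur, call. = FALSE)
      }
      seen <- c(seen, cur)
      cur <- if (as.character(cur) %in% names(parent_of)) {
        parent_of[[as.character(cur)]]
      } else {
        NA_integer_
      }
    }
  }
  docs <- list()
  for (i in seq_len(nrow(acc))) {
    row <- acc[i, ]
    pid <- row$parentNameUsageID
    if (is.na(pid)) next
    if (!pid %in% acc$taxonID) {
      warning("parentNameUsageID ", pid, " of taxon ", row$taxonID,
              " does not resolve to an accepted row; edge skipped",
              call. = FALSE)
      next
    }
    child <- gbif_iri(version$base_uuid, row$taxonID, "concept")
    parent <- gbif_iri(version$base_uuid, pid, "concept")
    stmt <- paste0("http://openbiodiv.net/", version$base_uuid, "-",
                   row$taxonID, "-rcc5")
    docs[[length(docs) + 1L]] <- dplyr::bind_rows(
      rdf_quads(g, child, "skos:broader", iri(parent)),
      rdf_quads(g, stmt, "rdf:type", iri("openbiodiv:RCC5Statement")),
      rdf_quads(g, stmt, rcc5_predicates$subject, iri(child)),
      rdf_quads(g, stmt, rcc5_predicates$object, iri(parent)),
      rdf_quads(g, stmt, rcc5_predicates$relation,
                iri(rcc5_vocabulary()[["ProperPart"]]))
    )
  }
  if (length(docs) == 0L) return(rdf_doc())
  rdf_doc(dplyr::bind_rows(docs))
}

#' Import a backbone taxonomy as taxonomic concepts
#'
#' Union of [concept_graph()] over accepted rows, [hierarchy_graph()],
#' the version resource, and synonym handling: a synonym row contributes
#' a `-scName` resource linked to its accepted concept at the name level
#' (`openbiodiv:hasSynonymName`), but no concept resource and no
#' hierarchy edge. Deterministic given `base_uuid`; a second import under
#' a new base UUID adds statements in its own named graph without
#' touching earlier versions.
#'
#' @param tsv TSV path or string (see [read_backbone()]).
#' @param citation Citation string for the concept labels.
#' @param base_uuid Optional base UUID (random when NULL).
#' @param quiet Passed to [read_backbone()].
#' @return A `triple_doc`.
#' @export
import_backbone <- function(tsv, citation, base_uuid = NULL, quiet = FALSE) {
  rows <- read_backbone(tsv, quiet = quiet)
  version <- backbone_version(citation, base_uuid)
  g <- version$graph_iri
  docs <- list(
    rdf_doc(dplyr::bind_rows(
      rdf_quads(g, version$version_iri, "rdf:type",
                iri("openbiodiv:BackboneVersion")),
      rdf_quads(g, version$version_iri, "dcterms:bibliographicCitation",
                lit(citation))
    ))
  )
  acc <- rows[is_accepted_status(rows$taxonomicStatus), , drop = FALSE]
  for (i in seq_len(nrow(acc))) {
    docs[[length(docs) + 1L]] <- concept_graph(acc[i, ], version)
  }
  docs[[length(docs) + 1L]] <- hierarchy_graph(rows, version)
  syn <- rows[!is_accepted_status(rows$taxonomicStatus), , drop = FALSE]
  for (i in seq_len(nrow(syn))) {
    row <- syn[i, ]
    target <- row$acceptedNameUsageID
    name <- gbif_iri(version$base_uuid, row$taxonID, "scientific_name")
    q <- dplyr::bind_rows(
      rdf_quads(g, name, "rdf:type", iri("openbiodiv:ScientificName")),
      rdf_quads(g, name, "rdfs:label", lit(backbone_name_label(row)))
    )
    if (!is.na(target) && target %in% acc$taxonID) {
      concept <- gbif_iri(version$base_uuid, target, "concept")
      q <- dplyr::bind_rows(
        q, rdf_quads(g, concept, "openbiodiv:hasSynonymName", iri(name)))
    }
    docs[[length(docs) + 1L]] <- rdf_doc(q)
  }
  rdf_union(!!!docs)
}
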