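# Post-submission update rules over the populated graph: replacement-name
# and related-name edges (inserted into the Updates named graph) and the
# name-validity decision procedure built on them. All pattern matching is
# evaluated directly on the quad table with relational joins.

updates_graph_iri <- "http://openbiodiv.net/Updates"

pred_iri <- function(curie) expand_curie(curie)

pred_pairs <- function(d, curie) {
  p <- pred_iri(curie)
  dplyr::select(
    dplyr::filter(d, .data$predicate == p, .data$is_iri),
    subject = "subject", object = "object")
}

lit_pairs <- function(d, curie) {
  p <- pred_iri(curie)
  dplyr::select(
    dplyr::filter(d, .data$predicate == p, !.data$is_iri),
    subject = "subject", value = "object", datatype = "datatype")
}

type_subjects <- function(d, class_curie) {
  cls <- expand_curie(class_curie)
  unique(d$subject[d$predicate == pred_iri("rdf:type") & d$is_iri &
                     d$object == cls])
}

#' Transitive closure of the containment relation
#'
#' @param doc A `triple_doc` or quad tibble.
#' @param max_steps Optional cap on path length (NULL = full closure).
#' @return Tibble with columns `ancestor`, `descendant`, `steps`.
#' @export
containment_closure <- function(doc, max_steps = NULL) {
  d <- tibble::as_tibble(doc)
  edges <- pred_pairs(d, "po:contains")
  closure <- dplyr::mutate(edges, steps = 1L)
  frontier <- closure
  repeat {
    if (!is.null(max_steps) && max(frontier$steps) >= max_steps) break
    nxt <- dplyr::inner_join(
      dplyr::select(frontier, ancestor_s = "subject", mid = "object",
                    steps = "steps"),
      dplyr::select(edges, mid = "subject", object = "object"),
      by = "mid", relationship = "many-to-many"
    )
    nxt <- dplyr::distinct(
      tibble::tibble(subject = nxt$ancestor_s, object = nxt$object,
                     steps = nxt$steps + 1L))
    new <- dplyr::anti_join(nxt, closure, by = c("subject", "object"))
    if (nrow(new) == 0L) break
    closure <- dplyr::bind_rows(closure, new)
    frontier <- new
  }
  dplyr::select(closure, ancestor = "subject", descendant = "object",
                steps = "steps")
}

#' Apply the replacement-name update rule
#'
#' A name B gets a `replacementName` edge to a name A when some taxonomic
#' name usage of A carries status `openbiodiv:ReplacementName` inside a
#' nomenclature section whose nomenclature citations list contains a
#' citation with a usage of B, and A and B share the same verbatim taxon
#' rank. Edges target the Updates graph; the rule is idempotent under the
#' document's set semantics.
#'
#' @param doc A `triple_doc` with converted articles.
#' @return Tibble of edges: `from_name` (B), `to_name` (A), `relation`.
#' @export
apply_replacement_rule <- function(doc) {
  d <- tibble::as_tibble(doc)
  status <- pred_pairs(d, "dwciri:taxonomicStatus")
  repl_status <- expand_curie("openbiodiv:ReplacementName")
  tnu1 <- unique(status$subject[status$object == repl_status])
  mentions <- pred_pairs(d, "pkm:mentions")
  labels <- lit_pairs(d, "rdfs:label")
  ranks <- lit_pairs(d, "dwc:verbatimTaxonRank")
  contains <- pred_pairs(d, "po:contains")
  nom_secs <- type_subjects(d, "openbiodiv:NomenclatureSection")
  cit_lists <- type_subjects(d, "openbiodiv:NomenclatureCitationsList")
  tnus <- type_subjects(d, "openbiodiv:TaxonomicNameUsage")

  # ?nomenclature po:contains ?tnu1 / ?citations; typed joins
  j <- dplyr::inner_join(
    dplyr::filter(contains, .data$subject %in% nom_secs,
                  .data$object %in% tnu1) |>
      dplyr::select(nomenclature = "subject", tnu1 = "object"),
    dplyr::filter(contains, .data$subject %in% nom_secs,
                  .data$object %in% cit_lists) |>
      dplyr::select(nomenclature = "subject", citations = "object"),
    by = "nomenclature", relationship = "many-to-many"
  )
  j <- dplyr::inner_join(
    j,
    dplyr::select(contains, citations = "subject", citation = "object"),
    by = "citations", relationship = "many-to-many"
  )
  j <- dplyr::inner_join(
    j,
    dplyr::select(contains, citation = "subject", tnu2 = "object"),
    by = "citation", relationship = "many-to-many"
  )
  j <- dplyr::filter(j, .data$tnu2 %in% tnus)
  j <- dplyr::inner_join(
    j, dplyr::select(mentions, tnu1 = "subject", name = "object"),
    by = "tnu1", relationship = "many-to-many")
  j <- dplyr::inner_join(
    j, dplyr::select(mentions, tnu2 = "subject", name2 = "object"),
    by = "tnu2", relationship = "many-to-many")
  # both names must have a label and the same rank
  j <- dplyr::semi_join(j, dplyr::select(labels, name = "subject"),
                        by = "name")
  j <- dplyr::semi_join(j, dplyr::select(labels, name2 = "subject"),
                        by = "name2")
  j <- dplyr::inner_join(
    j, dplyr::select(ranks, name = "subject", rank = "value"),
    by = "name", relationship = "many-to-many")
  j <- dplyr::inner_join(
    j, dplyr::select(ranks, name2 = "subject", rank = "value"),
    by = c("name2", "rank"), relationship = "many-to-many")
  dplyr::distinct(
    tibble::tibble(from_name = j$name2, to_name = j$name,
                   relation = "replacementName"))
}

#' Apply the related-name update rule
#'
#' Two distinct scientific names are related when both are mentioned by
#' taxonomic name usages inside the same nomenclature section of a
#' treatment. Both orders arise from the pattern, so the materialized
#' relation is symmetric: a section mentioning k distinct names yields
#' k(k-1) directed edges.
#'
#' @param doc A `triple_doc` with converted articles.
#' @return Tibble of edges: `from_name`, `to_name`, `relation`.
#' @export
apply_related_rule <- function(doc) {
  d <- tibble::as_tibble(doc)
  # "mentioned in the nomenclature section" covers usages at any depth
  # below the section (the citations list nests its usages two levels
  # down), so the containment closure is used rather than one step
  closure <- containment_closure(d)
  nom_secs <- type_subjects(d, "openbiodiv:NomenclatureSection")
  tnus <- type_subjects(d, "openbiodiv:TaxonomicNameUsage")
  mentions <- pred_pairs(d, "pkm:mentions")
  in_nom <- dplyr::select(
    dplyr::filter(closure, .data$ancestor %in% nom_secs,
                  .data$descendant %in% tnus),
    subject = "ancestor", object = "descendant")
  m <- dplyr::inner_join(
    dplyr::select(in_nom, nom = "subject", tnu = "object"),
    dplyr::select(mentions, tnu = "subject", name = "object"),
    by = "tnu", relationship = "many-to-many")
  pairs <- dplyr::inner_join(
    dplyr::select(m, nom = "nom", name = "name"),
    dplyr::select(m, nom = "nom", name2 = "name"),
    by = "nom", relationship = "many-to-many")
  pairs <- dplyr::filter(pairs, .data$name != .data$name2)
  dplyr::distinct(
    tibble::tibble(from_name = pairs$name2, to_name = pairs$name,
                   relation = "relatedName"))
}

#' Insert update-rule edges into the Updates named graph
#'
#' Runs both rules and materializes their edges as quads in the dedicated
#' Updates graph. Re-running on the result adds nothing (idempotent).
#'
#' @param doc A `triple_doc`.
#' @return List: `doc` (input plus edges), `replacement` and `related`
#'   edge tibbles.
#' @export
postprocess_graph <- function(doc) {
  repl <- apply_replacement_rule(doc)
  rel <- apply_related_rule(doc)
  edge_quads <- function(edges, predicate) {
    if (nrow(edges) == 0L) return(NULL)
    dplyr::bind_rows(purrr::map(seq_len(nrow(edges)), function(i) {
      rdf_quads(updates_graph_iri, edges$from_name[i],
                paste0("openbiodiv:", predicate), iri(edges$to_name[i]))
    }))
  }
  out <- doc
  rq <- edge_quads(repl, "replacementName")
  if (!is.null(rq)) out <- rdf_add(out, rq)
  lq <- edge_quads(rel, "relatedName")
  if (!is.null(lq)) out <- rdf_add(out, lq)
  list(doc = out, replacement = repl, related = rel)
}

name_iris_for_label <- function(d, label, require_type = TRUE) {
  labels <- lit_pairs(d, "rdfs:label")
  hits <- unique(labels$subject[labels$value == label])
  if (require_type) {
    sci <- type_subjects(d, "openbiodiv:ScientificName")
    hits <- intersect(hits, sci)
  }
  hits
}

#' Has a name been replaced?
#'
#' `one_step` mode mirrors the catalogue's ASK query exactly: true when
#' the name has an outgoing `replacementName` edge whose target has no
#' further outgoing edge. `transitive` mode implements the full
#' no-loops criterion: true when the name has at least one outgoing edge
#' and no chain of `replacementName` edges leads back to it.
#'
#' @param doc A `triple_doc` (updates applied).
#' @param label Exact `rdfs:label` of the name.
#' @param mode `"transitive"` (default) or `"one_step"`.
#' @return TRUE or FALSE (FALSE with a warning for an unknown label).
#' @export
is_replaced <- function(doc, label, mode = c("transitive", "one_step")) {
  mode <- match.arg(mode)
  d <- tibble::as_tibble(doc)
  starts <- name_iris_for_label(d, label)
  if (length(starts) == 0L) {
    warning("no scientific name labelled '", label, "'", call. = FALSE)
    return(FALSE)
  }
  edges <- pred_pairs(d, "openbiodiv:replacementName")
  if (mode == "one_step") {
    for (s in starts) {
      targets <- edges$object[edges$subject == s]
      for (t in targets) {
        if (!any(edges$subject == t)) return(TRUE)
      }
    }
    return(FALSE)
  }
  for (s in starts) {
    targets <- edges$object[edges$subject == s]
    if (length(targets) == 0L) next
    # does any edge path return to s?
    seen <- character(0)
    stack <- targets
    loop <- FALSE
    while (length(stack) > 0L) {
      cur <- stack[[1]]
      stack <- stack[-1]
      if (cur == s) { loop <- TRUE; break }
      if (cur %in% seen) next
      seen <- c(seen, cur)
      stack <- c(stack, edges$object[edges$subject == cur])
    }
    if (!loop) return(TRUE)
  }
  FALSE
}

parse_quad_date <- function(value, datatype) {
  if (!is.na(datatype) &&
      datatype == expand_curie("xsd:date")) {
    return(as.Date(value))
  }
  if (grepl("^\\d{4}-\\d{2}-\\d{2}$", value)) return(as.Date(value))
  NA
}

tnu_article_dates <- function(d) {
  closure <- containment_closure(d)
  dates <- lit_pairs(d, "prism:publicationDate")
  j <- dplyr::inner_join(
    dplyr::select(closure, article = "ancestor", tnu = "descendant"),
    dplyr::select(dates, article = "subject", date_str = "value",
                  datatype = "datatype"),
    by = "article", relationship = "many-to-many")
  j$date <- as.Date(vapply(seq_len(nrow(j)), function(i) {
    as.character(parse_quad_date(j$date_str[i], j$datatype[i]))
  }, character(1)))
  j
}

#' Is a name currently considered unavailable?
#'
#' True when some usage of the name carries status
#' `openbiodiv:UnavailableName` in an article dated D and no usage of the
#' name carries `openbiodiv:AvailableName` in an article dated strictly
#' later than D. Usages in undated articles are excluded with a warning.
#'
#' @inheritParams is_replaced
#' @return TRUE or FALSE.
#' @export
is_unavailable <- function(doc, label) {
  d <- tibble::as_tibble(doc)
  names_ <- name_iris_for_label(d, label, require_type = FALSE)
  if (length(names_) == 0L) return(FALSE)
  mentions <- pred_pairs(d, "pkm:mentions")
  status <- pred_pairs(d, "dwciri:taxonomicStatus")
  unav <- expand_curie("openbiodiv:UnavailableName")
  avail <- expand_curie("openbiodiv:AvailableName")
  tnus <- mentions$subject[mentions$object %in% names_]
  st <- dplyr::filter(status, .data$subject %in% tnus)
  if (!any(st$object == unav)) return(FALSE)
  ad <- tnu_article_dates(d)
  dated <- function(tnu_set) {
    rows <- ad[ad$tnu %in% tnu_set, , drop = FALSE]
    lost <- setdiff(tnu_set, rows$tnu[!is.na(rows$date)])
    if (length(lost) > 0L) {
      warning(length(lost), " usage(s) in undated articles excluded from ",
              "the availability comparison", call. = FALSE)
    }
    rows$date[!is.na(rows$date)]
  }
  unav_dates <- dated(st$subject[st$object == unav])
  avail_dates <- dated(st$subject[st$object == avail])
  if (length(unav_dates) == 0L) return(FALSE)
  any(vapply(unav_dates, function(dte) {
    !any(avail_dates > dte)
  }, logical(1)))
}

#' Decide the validity of a taxonomic name
#'
#' A name is invalid iff at least one invalidation criterion holds: it
#' has been replaced (transitively, with no loop back) or it has been
#' made unavailable without a later revalidation.
#'
#' @inheritParams is_replaced
#' @return A one-row tibble: `name_label`, `valid`, `replaced`,
#'   `unavailable`, `reasons`.
#' @export
check_validity <- function(doc, label) {
  replaced <- suppressWarnings(is_replaced(doc, label, mode = "transitive"))
  unavailable <- suppressWarnings(is_unavailable(doc, label))
  reasons <- c(if (replaced) "replaced", if (unavailable) "unavailable")
  tibble::tibble(
    name_label = label,
    valid = length(reasons) == 0L,
    replaced = replaced,
    unavailable = unavailable,
    reasons = paste(reasons, collapse = ";")
  )
}
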