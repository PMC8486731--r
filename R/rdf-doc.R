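#' RDF terms: IRIs and literals
#'
#' `iri()` marks a string as an IRI reference (CURIEs are expanded against
#' the default prefix table when the quad is built); `lit()` builds a typed,
#' tagged or plain literal. A literal may carry a datatype or a language tag
#' but never both. Literal lexical forms are NFC-normalized on construction.
#'
#' @param value IRI string or CURIE.
#' @param lexical Literal lexical form.
#' @param datatype Optional datatype IRI or CURIE (e.g. `"xsd:date"`).
#' @param lang Optional language tag.
#' @return An `rdf_iri` / `rdf_lit` object.
#' @export
#' @examples
#' iri("fabio:JournalArticle")
#' lit("2016-07-08", datatype = "xsd:date")
iri <- function(value) {
  stopifnot(is.character(value), length(value) == 1L, !is.na(value), nzchar(value))
  structure(list(value = value), class = "rdf_iri")
}

#' @rdname iri
#' @export
lit <- function(lexical, datatype = NULL, lang = NULL) {
  if (!is.null(datatype) && !is.null(lang)) {
    stop("a literal may have a datatype or a language tag, not both",
         call. = FALSE)
  }
  structure(
    list(
      lexical = stringi::stri_trans_nfc(as.character(lexical)),
      datatype = datatype,
      lang = lang
    ),
    class = "rdf_lit"
  )
}

quad_cols <- c("graph", "subject", "predicate", "object", "is_iri",
               "datatype", "lang")

empty_quads <- function() {
  tibble::tibble(
    graph = character(), subject = character(), predicate = character(),
    object = character(), is_iri = logical(),
    datatype = character(), lang = character()
  )
}

#' Create an RDF quad document
#'
#' A `triple_doc` is a tibble of named-graph statements (quads) with set
#' semantics: adding an already-present quad is a no-op. Columns are
#' `graph`, `subject`, `predicate` (absolute IRIs), `object`, `is_iri`
#' (whether the object is an IRI), `datatype` and `lang` (for literals).
#' The namespace prefix table travels as an attribute.
#'
#' @param quads Optional tibble of quads (as produced by [rdf_quads()]).
#' @param namespaces Named character vector of prefixes.
#' @return A `triple_doc` tibble.
#' @export
#' @examples
#' doc <- rdf_doc() |>
#'   rdf_add("openbiodiv:g1", "openbiodiv:s1", "rdf:type", iri("foaf:Person"))
#' nrow(doc)
rdf_doc <- function(quads = NULL, namespaces = rdf_prefixes()) {
  q <- if (is.null(quads)) empty_quads() else dplyr::distinct(quads[quad_cols])
  structure(
    tibble::new_tibble(q, class = "triple_doc"),
    namespaces = namespaces
  )
}

doc_namespaces <- function(doc) {
  ns <- attr(doc, "namespaces")
  if (is.null(ns)) rdf_prefixes() else ns
}

as_object_fields <- function(object, namespaces) {
  if (inherits(object, "rdf_iri")) {
    list(object = expand_curie(object$value, namespaces), is_iri = TRUE,
         datatype = NA_character_, lang = NA_character_)
  } else if (inherits(object, "rdf_lit")) {
    dt <- if (is.null(object$datatype)) NA_character_ else
      expand_curie(object$datatype, namespaces)
    lg <- if (is.null(object$lang)) NA_character_ else object$lang
    list(object = object$lexical, is_iri = FALSE, datatype = dt, lang = lg)
  } else if (is.character(object) && length(object) == 1L) {
    # bare strings are treated as IRIs/CURIEs: literals must be explicit
    list(object = expand_curie(object, namespaces), is_iri = TRUE,
         datatype = NA_character_, lang = NA_character_)
  } else {
    stop("object must be iri(), lit() or a single IRI string", call. = FALSE)
  }
}

#' Build quad rows
#'
#' Vectorized over `object` when given a list of terms; `graph`, `subject`
#' and `predicate` are recycled. All four positions must be non-empty.
#'
#' @param graph,subject,predicate IRIs or CURIEs.
#' @param object An [iri()], [lit()], IRI string, or list of such terms.
#' @param namespaces Prefix table used for expansion.
#' @return A quad tibble suitable for [rdf_add()].
#' @export
rdf_quads <- function(graph, subject, predicate, object,
                      namespaces = rdf_prefixes()) {
  objects <- if (is.list(object) && !inherits(object, c("rdf_iri", "rdf_lit"))) {
    object
  } else {
    list(object)
  }
  g <- expand_curie(graph, namespaces)
  s <- expand_curie(subject, namespaces)
  p <- expand_curie(predicate, namespaces)
  if (!nzchar(g) || !nzchar(s) || !nzchar(p)) {
    stop("graph, subject and predicate must be non-empty", call. = FALSE)
  }
  k <- length(objects)
  obj <- character(k); isi <- logical(k)
  dt <- character(k); lg <- character(k)
  for (i in seq_len(k)) {
    f <- as_object_fields(objects[[i]], namespaces)
    if (is.na(f$object) || (f$is_iri && !nzchar(f$object))) {
      stop("quad object must be non-empty", call. = FALSE)
    }
    obj[i] <- f$object; isi[i] <- f$is_iri
    dt[i] <- f$datatype; lg[i] <- f$lang
  }
  tibble::new_tibble(list(
    graph = rep(g, k), subject = rep(s, k), predicate = rep(p, k),
    object = obj, is_iri = isi, datatype = dt, lang = lg
  ), nrow = k)
}

#' Add quads to a document (set semantics)
#'
#' Either pass `graph`/`subject`/`predicate`/`object` as in [rdf_quads()],
#' or pass a prebuilt quad tibble / `triple_doc` as the second argument.
#' Duplicate quads are dropped, so adding the same quad twice grows the
#' document by one row in total.
#'
#' @param doc A `triple_doc`.
#' @param graph A graph IRI, or a quad tibble to merge.
#' @param subject,predicate,object See [rdf_quads()].
#' @return The updated `triple_doc`.
#' @export
rdf_add <- function(doc, graph, subject = NULL, predicate = NULL,
                    object = NULL) {
  ns <- doc_namespaces(doc)
  new <- if (is.data.frame(graph)) {
    graph[quad_cols]
  } else {
    rdf_quads(graph, subject, predicate, object, ns)
  }
  merged <- dplyr::distinct(dplyr::bind_rows(tibble::as_tibble(doc), new))
  rdf_doc(merged, namespaces = ns)
}

#' Merge several quad documents into one
#'
#' @param ... `triple_doc`s or quad tibbles.
#' @param namespaces Prefix table for the result.
#' @return A `triple_doc` holding the union of the quad sets.
#' @export
rdf_union <- function(..., namespaces = rdf_prefixes()) {
  parts <- purrr::compact(rlang::list2(...))
  if (length(parts) == 0L) return(rdf_doc(namespaces = namespaces))
  merged <- dplyr::distinct(
    dplyr::bind_rows(purrr::map(parts, ~ tibble::as_tibble(.x)[quad_cols]))
  )
  rdf_doc(merged, namespaces = namespaces)
}

#' @export
print.triple_doc <- function(x, ...) {
  cat("<triple_doc> ", nrow(x), " quads in ",
      dplyr::n_distinct(x$graph), " graph(s)\n", sep = "")
  NextMethod()
}

#' Quad-set equality of two documents
#'
#' @param a,b `triple_doc`s or quad tibbles.
#' @return TRUE iff the two quad sets are identical.
#' @export
rdf_equal <- function(a, b) {
  key <- function(d) {
    d <- tibble::as_tibble(d)[quad_cols]
    sort(do.call(paste, c(lapply(d, function(col) ifelse(is.na(col), "\x01", col)),
                          sep = "\x02")))
  }
  identical(key(a), key(b))
}

#' One-row summary of a quad document
#'
#' @param x A `triple_doc`.
#' @param ... Unused.
#' @return A tibble with quad, graph, subject and typed-resource counts.
#' @export
glance.triple_doc <- function(x, ...) {
  rdf_type <- expand_curie("rdf:type", doc_namespaces(x))
  tibble::tibble(
    n_quads = nrow(x),
    n_graphs = dplyr::n_distinct(x$graph),
    n_subjects = dplyr::n_distinct(x$subject),
    n_typed = dplyr::n_distinct(x$subject[x$predicate == rdf_type])
  )
}

#' Tidy view of a quad document with compacted CURIEs
#'
#' @param x A `triple_doc`.
#' @param ... Unused.
#' @return A tibble with graph/subject/predicate/object compacted to CURIEs.
#' @export
tidy.triple_doc <- function(x, ...) {
  ns <- doc_namespaces(x)
  tibble::tibble(
    graph = compact_iri(x$graph, ns),
    subject = compact_iri(x$subject, ns),
    predicate = compact_iri(x$predicate, ns),
    object = ifelse(x$is_iri, compact_iri(x$object, ns), x$object),
    is_iri = x$is_iri
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Bar chart of resource types in a quad document
#'
#' Counts subjects per `rdf:type` object and draws a horizontal bar chart —
#' a quick census of what a conversion produced.
#'
#' @param object A `triple_doc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triple_doc <- function(object, ...) {
  ns <- doc_namespaces(object)
  rdf_type <- expand_curie("rdf:type", ns)
  counts <- tibble::as_tibble(object) |>
    dplyr::filter(.data$predicate == rdf_type) |>
    dplyr::count(type = compact_iri(.data$object, ns), sort = TRUE)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$n,
                               y = stats::reorder(.data$type, .data$n))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "resources", y = NULL,
                  title = "Typed resources in the quad document")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
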