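# The recursive extractor: atoms extraction, constructor dispatch, and a
# divide-and-conquer step over child nodes, driven entirely by the
# declarative schema.

schema_ns <- function(schema) {
  ns <- schema$xmlns
  if (is.null(ns) || length(ns) == 0L) return(character(0))
  unlist(ns)
}

#' Extract the atoms of an XML node
#'
#' Atoms are the text fields (element text or attribute values) reachable
#' from the node by the relative XPath locations the node spec declares.
#' Atoms whose XPath matches nothing are absent from the result, not
#' null-valued.
#'
#' @param node An `xml2` node.
#' @param spec A node spec (entry of a schema's `nodes`).
#' @param ns Named character vector of XML namespace prefixes (from the
#'   schema's `xmlns`).
#' @return Named list mapping atom name to character vector of values.
#' @export
extract_atoms <- function(node, spec, ns = character(0)) {
  out <- list()
  for (nm in names(spec$atoms)) {
    atom <- spec$atoms[[nm]]
    hits <- if (length(ns) > 0L) {
      xml2::xml_find_all(node, atom$location, ns = ns)
    } else {
      xml2::xml_find_all(node, atom$location)
    }
    if (length(hits) > 0L) {
      vals <- trimws(xml2::xml_text(hits))
      vals <- vals[nzchar(vals)]
      if (length(vals) > 0L) out[[nm]] <- vals
    }
  }
  out
}

#' Resolve author affiliations by cross-reference matching
#'
#' The affiliation of an author cannot be addressed with a single XPath:
#' the `xref/@rid` of the author must be matched against the document's
#' `aff` elements. For each `xref` with `ref-type="aff"` and rid R, the
#' matching `aff` is the first of: `@id == R`, `@id == "A" + R`, or label
#' text equal to R. Published XML mixes these conventions, hence the
#' cascade.
#'
#' @param author_node The `contrib` element.
#' @param document_root Root node of the document (searched for `aff`).
#' @param quiet Suppress the warning on unresolvable rids.
#' @return Character vector of affiliation address strings.
#' @export
resolve_affiliations <- function(author_node, document_root, quiet = FALSE) {
  xrefs <- xml2::xml_find_all(author_node, "./xref[@ref-type='aff']")
  if (length(xrefs) == 0L) return(character(0))
  affs <- xml2::xml_find_all(document_root, "//aff")
  aff_ids <- xml2::xml_attr(affs, "id")
  aff_labels <- vapply(affs, function(a) {
    lab <- xml2::xml_find_first(a, "./label")
    if (inherits(lab, "xml_missing")) NA_character_ else
      trimws(xml2::xml_text(lab))
  }, character(1))
  aff_text <- vapply(affs, function(a) {
    addr <- xml2::xml_find_first(a, "./addr-line")
    node <- if (inherits(addr, "xml_missing")) a else addr
    trimws(xml2::xml_text(node))
  }, character(1))
  out <- character(0)
  for (x in xrefs) {
    rid <- xml2::xml_attr(x, "rid")
    hit <- which(aff_ids == rid)
    if (length(hit) == 0L) hit <- which(aff_ids == paste0("A", rid))
    if (length(hit) == 0L) hit <- which(aff_labels == rid)
    if (length(hit) == 0L) {
      if (!quiet) {
        warning("affiliation reference '", rid, "' unresolvable; omitted",
                call. = FALSE)
      }
      next
    }
    out <- c(out, aff_text[[hit[[1]]]])
  }
  out
}

#' Recursively convert an XML node to RDF
#'
#' One Extractor step: extract the node's atoms, dispatch to its
#' constructor, then recurse into every matched child node (divide and
#' conquer), each child receiving this node's IRI appended to the
#' ancestor chain. The union of all constructor outputs is returned.
#'
#' @param node `xml2` node matching `spec$location`.
#' @param spec Node spec.
#' @param schema Full schema (for child specs and namespaces).
#' @param ctx Context list: `graph_iri`, `article_iri`, `article_key`,
#'   `parent_chain` (list of `list(iri, resource_type)`),
#'   `backbone_match`, `status_mapping`, `quiet`.
#' @param store An [id_store()].
#' @return `list(doc, iri)`.
#' @export
extract_node <- function(node, spec, schema, ctx, store) {
  ns <- schema_ns(schema)
  atoms <- extract_atoms(node, spec, ns)
  if (isTRUE(spec$resolve_affiliations)) {
    aff <- resolve_affiliations(node, xml2::xml_root(node),
                                quiet = isTRUE(ctx$quiet))
    if (length(aff) > 0L) atoms$affiliation <- aff
  }
  ctx$node_key <- paste0(ctx$article_key, "|", xml2::xml_path(node))
  ctor <- constructor_registry()[[spec$constructor]]
  result <- tryCatch(
    ctor(atoms, ctx, store, spec),
    error = function(e) {
      stop("constructor '", spec$constructor, "' failed at ",
           xml2::xml_path(node), ": ", conditionMessage(e), call. = FALSE)
    }
  )
  if (is.null(result$iri)) {
    return(list(doc = result$doc, iri = NULL))
  }
  parts <- list(tibble::as_tibble(result$doc))
  if (spec$constructor == "article") {
    ctx$graph_iri <- result$graph
    ctx$article_iri <- result$iri
  }
  child_ctx <- ctx
  child_ctx$parent_chain <- c(ctx$parent_chain,
                              list(list(iri = result$iri,
                                        resource_type = spec$resource_type)))
  for (child_name in spec$children) {
    child_spec <- schema$nodes[[child_name]]
    hits <- if (length(ns) > 0L) {
      xml2::xml_find_all(node, child_spec$location, ns = ns)
    } else {
      xml2::xml_find_all(node, child_spec$location)
    }
    for (h in hits) {
      sub <- extract_node(h, child_spec, schema, child_ctx, store)
      parts[[length(parts) + 1L]] <- tibble::as_tibble(sub$doc)
    }
  }
  list(doc = rdf_doc(dplyr::bind_rows(parts)), iri = result$iri)
}

article_key_of <- function(root, schema, ns) {
  spec <- schema$nodes[[schema$root]]
  atoms <- extract_atoms(root, spec, ns)
  doi <- atoms$doi
  title <- atoms$title
  key <- if (!is.null(doi) && length(doi) > 0L) doi[[1]] else
    if (!is.null(title) && length(title) > 0L) title[[1]] else NULL
  if (is.null(key)) {
    stop("article has neither a DOI nor a title and cannot be identified",
         call. = FALSE)
  }
  normalize_label(key)
}

#' Convert a whole article document to RDF
#'
#' Runs the Extractor on the document's root node. All quads land in the
#' article's named graph (the graph IRI is the article IRI), and every
#' non-article resource is reachable from the article via containment or
#' an explicit link, so converted articles form connected graphs.
#' Identifier minting is idempotent against the store: converting the
#' same document twice mints nothing the second time.
#'
#' @param xml Path to an XML file, an XML string, or an `xml2` document.
#' @param schema A schema from [load_schema()], or a dialect name.
#' @param store An [id_store()]; defaults to a fresh in-memory store.
#' @param backbone_match Optional named character vector mapping name
#'   labels to backbone `-scName` IRIs (emitted as
#'   `openbiodiv:hasGbifTaxon` links).
#' @param status_mapping Named character vector from
#'   [default_status_mapping()].
#' @param quiet Suppress extraction warnings.
#' @return A `triple_doc` with the article graph.
#' @export
parse_article <- function(xml, schema = "taxpub", store = id_store(),
                          backbone_match = NULL,
                          status_mapping = default_status_mapping(),
                          quiet = FALSE) {
  if (is.character(schema)) schema <- load_schema(schema)
  doc <- if (inherits(xml, "xml_document")) {
    xml
  } else if (is.character(xml) && length(xml) == 1L &&
             !grepl("^\\s*<", xml)) {
    xml2::read_xml(xml)
  } else {
    xml2::read_xml(paste(xml, collapse = "\n"))
  }
  ns <- schema_ns(schema)
  root_spec <- schema$nodes[[schema$root]]
  root <- if (length(ns) > 0L) {
    xml2::xml_find_first(doc, root_spec$location, ns = ns)
  } else {
    xml2::xml_find_first(doc, root_spec$location)
  }
  if (inherits(root, "xml_missing")) {
    stop("document root does not match the ", schema$dialect,
         " schema (expected ", root_spec$location, ")", call. = FALSE)
  }
  ctx <- list(
    graph_iri = NULL, article_iri = NULL,
    article_key = article_key_of(root, schema, ns),
    parent_chain = list(),
    backbone_match = backbone_match,
    status_mapping = status_mapping,
    quiet = quiet
  )
  res <- extract_node(root, root_spec, schema, ctx, store)
  res$doc
}
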