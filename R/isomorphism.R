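uuid_regex <- "^[0-9A-Fa-f]{8}-[0-9A-Fa-f]{4}-[0-9A-Fa-f]{4}-[0-9A-Fa-f]{4}-[0-9A-Fa-f]{12}$"

#' Default predicate selecting renameable instance IRIs
#'
#' Instance IRIs minted in the openbiodiv namespace have the form
#' `http://openbiodiv.net/<UUID>`; only these are subject to renaming when
#' graphs are compared. Suffixed backbone IRIs and vocabulary IRIs are
#' fixed.
#'
#' @param x Character vector of IRIs.
#' @return Logical vector.
#' @export
is_instance_iri <- function(x) {
  startsWith(x, "http://openbiodiv.net/") &
    grepl(uuid_regex, substring(x, nchar("http://openbiodiv.net/") + 1L))
}

quad_signature_df <- function(d, renameable) {
  # replaces renameable IRIs with a placeholder, for signature computation
  mask <- function(col, is_iri_col = TRUE) {
    ren <- if (is_iri_col) renameable(col) else rep(FALSE, length(col))
    ifelse(ren, "\x7fVAR", col)
  }
  tibble::tibble(
    graph = mask(d$graph),
    subject = mask(d$subject),
    predicate = mask(d$predicate),
    object = ifelse(d$is_iri & renameable(d$object), "\x7fVAR", d$object),
    is_iri = d$is_iri, datatype = d$datatype, lang = d$lang
  )
}

node_positions <- function(d, node) {
  # string describing where `node` occurs in each quad, with other
  # renameable IRIs hidden
  hits <- d$graph == node | d$subject == node |
    (d$is_iri & d$object == node)
  d[hits, , drop = FALSE]
}

refine_colors <- function(d, nodes, renameable) {
  colors <- stats::setNames(rep("0", length(nodes)), nodes)
  repeat {
    newcolors <- vapply(nodes, function(v) {
      rows <- node_positions(d, v)
      if (nrow(rows) == 0L) return("isolated")
      sig <- vapply(seq_len(nrow(rows)), function(i) {
        r <- rows[i, ]
        role <- paste0(
          if (r$graph == v) "G" else "",
          if (r$subject == v) "S" else "",
          if (r$is_iri && r$object == v) "O" else ""
        )
        part <- function(x, is_iri = TRUE) {
          if (x %in% nodes) paste0("~", colors[[x]]) else x
        }
        paste(role, part(r$graph), part(r$subject), r$predicate,
              if (r$is_iri) part(r$object) else
                paste0("L:", r$object, ":", r$datatype, ":", r$lang),
              sep = "|")
      }, character(1))
      paste(sort(sig), collapse = "\n")
    }, character(1))
    # canonicalize to small ids (sorted signature order, stable)
    sigs <- sort(unique(newcolors))
    canon <- stats::setNames(as.character(seq_along(sigs)), sigs)
    newcolors <- stats::setNames(unname(canon[newcolors]), nodes)
    # stop when the induced partition stabilizes
    part <- function(cl) {
      unname(lapply(split(nodes, cl[nodes]), sort))
    }
    old_part <- part(colors)
    new_part <- part(newcolors)
    same <- length(old_part) == length(new_part) &&
      identical(sort(vapply(old_part, paste, character(1),
                            collapse = "\x01")),
                sort(vapply(new_part, paste, character(1),
                            collapse = "\x01")))
    colors <- newcolors
    if (same) break
  }
  colors
}

quad_keys <- function(d) {
  do.call(paste, c(lapply(d[quad_cols], function(col)
    ifelse(is.na(col), "\x01", col)), sep = "\x02"))
}

apply_mapping <- function(d, mapping) {
  swap <- function(col) {
    hit <- col %in% names(mapping)
    col[hit] <- unname(mapping[col[hit]])
    col
  }
  d$graph <- swap(d$graph)
  d$subject <- swap(d$subject)
  d$object[d$is_iri] <- swap(d$object[d$is_iri])
  d
}

#' Test isomorphism of two quad documents under instance-IRI renaming
#'
#' Two documents are isomorphic when a bijection over their renameable
#' IRIs (by default, minted openbiodiv UUID IRIs; see [is_instance_iri()])
#' maps one quad set exactly onto the other. Vocabulary IRIs and literals
#' must match verbatim. The search uses iterated color refinement to
#' partition candidates, then backtracking within color classes.
#'
#' @param a,b `triple_doc`s.
#' @param renameable Predicate over IRI character vectors.
#' @param ignore_graph If TRUE, graph IRIs are dropped before comparison
#'   (useful when comparing a conversion against a printed triple block
#'   that carries no named graph).
#' @return TRUE or FALSE.
#' @export
rdf_isomorphic <- function(a, b, renameable = is_instance_iri,
                           ignore_graph = FALSE) {
  da <- tibble::as_tibble(a)[quad_cols]
  db <- tibble::as_tibble(b)[quad_cols]
  if (ignore_graph) {
    da$graph <- "urn:x-graph"
    db$graph <- "urn:x-graph"
    da <- dplyr::distinct(da)
    db <- dplyr::distinct(db)
  }
  if (nrow(da) != nrow(db)) return(FALSE)
  iris <- function(d) unique(c(d$graph, d$subject, d$object[d$is_iri]))
  va <- iris(da); va <- va[renameable(va)]
  vb <- iris(db); vb <- vb[renameable(vb)]
  if (length(va) != length(vb)) return(FALSE)
  ren <- function(x) renameable(x)
  # fixed parts must agree as multisets
  if (!identical(sort(quad_keys(quad_signature_df(da, ren))),
                 sort(quad_keys(quad_signature_df(db, ren))))) {
    return(FALSE)
  }
  if (length(va) == 0L) {
    return(identical(sort(quad_keys(da)), sort(quad_keys(db))))
  }
  ca <- refine_colors(da, va, ren)
  cb <- refine_colors(db, vb, ren)
  if (!identical(sort(unname(ca)), sort(unname(cb)))) return(FALSE)
  target <- sort(quad_keys(db))
  # order nodes by ascending candidate count
  cand <- lapply(va, function(v) vb[cb[vb] == ca[[v]]])
  names(cand) <- va
  order_nodes <- va[order(vapply(cand, length, integer(1)))]
  assign_next <- function(idx, mapping, used) {
    if (idx > length(order_nodes)) {
      return(identical(sort(quad_keys(apply_mapping(da, mapping))), target))
    }
    v <- order_nodes[[idx]]
    for (w in cand[[v]]) {
      if (w %in% used) next
      mapping[[v]] <- w
      if (assign_next(idx + 1L, mapping, c(used, w))) return(TRUE)
    }
    FALSE
  }
  assign_next(1L, stats::setNames(character(0), character(0)), character(0))
}

#' Does one document contain a subgraph isomorphic to another?
#'
#' Looks for an injective mapping of the renameable IRIs of `small` into
#' the IRIs of `big` under which every quad of `small` (graph position
#' ignored) appears in `big`. Used to check conversions against printed
#' reference triple blocks, which show only the salient statements.
#'
#' @param big,small `triple_doc`s.
#' @param renameable Predicate over IRI character vectors.
#' @return TRUE or FALSE.
#' @export
rdf_contains_isomorphic <- function(big, small,
                                    renameable = is_instance_iri) {
  db <- tibble::as_tibble(big)[quad_cols]
  ds <- tibble::as_tibble(small)[quad_cols]
  db$graph <- "urn:x-graph"
  ds$graph <- "urn:x-graph"
  db <- dplyr::distinct(db)
  ds <- dplyr::distinct(ds)
  iris <- function(d) unique(c(d$subject, d$object[d$is_iri]))
  vs <- iris(ds); vs <- vs[renameable(vs)]
  vb <- iris(db); vb <- vb[renameable(vb)]
  big_keys <- quad_keys(db)
  if (length(vs) == 0L) {
    return(all(quad_keys(ds) %in% big_keys))
  }
  # candidates: any big instance IRI is allowed; prune by per-node degree
  deg <- function(d, v) sum(d$subject == v | (d$is_iri & d$object == v))
  cand <- lapply(vs, function(v) {
    dv <- deg(ds, v)
    vb[vapply(vb, function(w) deg(db, w) >= dv, logical(1))]
  })
  names(cand) <- vs
  order_nodes <- vs[order(vapply(cand, length, integer(1)))]
  assign_next <- function(idx, mapping, used) {
    if (idx > length(order_nodes)) {
      return(all(quad_keys(apply_mapping(ds, mapping)) %in% big_keys))
    }
    v <- order_nodes[[idx]]
    for (w in cand[[v]]) {
      if (w %in% used) next
      mapping[[v]] <- w
      # partial check: quads of ds fully mapped so far must be present
      part <- apply_mapping(ds, mapping)
      mapped_rows <- !(part$subject %in% vs) &
        !(part$is_iri & part$object %in% vs)
      if (all(quad_keys(part)[mapped_rows] %in% big_keys)) {
        if (assign_next(idx + 1L, mapping, c(used, w))) return(TRUE)
      }
    }
    FALSE
  }
  assign_next(1L, stats::setNames(character(0), character(0)), character(0))
}
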