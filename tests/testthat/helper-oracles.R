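# Independent oracles used across the suite. These deliberately avoid the
# package's own join/backtracking machinery: brute-force loops and
# exhaustive enumeration at small n.

rdf_type_iri <- expand_curie("rdf:type")

# per-type census of a converted graph (counts typed subjects per class)
type_census <- function(doc) {
  d <- tibble::as_tibble(doc)
  types <- d[d$predicate == rdf_type_iri & d$is_iri, ]
  tab <- table(compact_iri(types$object))
  stats::setNames(as.integer(tab), names(tab))
}

expect_census_matches <- function(doc, type_counts) {
  got <- type_census(doc)
  for (k in names(type_counts)) {
    g <- if (k %in% names(got)) got[[k]] else 0L
    expect_equal(g, unname(type_counts[[k]]),
                 info = paste("type census for", k))
  }
}

# sp / obj pairs for a predicate, raw loops (no dplyr)
oracle_pairs <- function(doc, curie) {
  d <- tibble::as_tibble(doc)
  p <- expand_curie(curie)
  keep <- d$predicate == p & d$is_iri
  data.frame(s = d$subject[keep], o = d$object[keep],
             stringsAsFactors = FALSE)
}

oracle_lit <- function(doc, curie) {
  d <- tibble::as_tibble(doc)
  p <- expand_curie(curie)
  keep <- d$predicate == p & !d$is_iri
  data.frame(s = d$subject[keep], v = d$object[keep],
             stringsAsFactors = FALSE)
}

oracle_typed <- function(doc, class_curie) {
  d <- tibble::as_tibble(doc)
  cls <- expand_curie(class_curie)
  unique(d$subject[d$predicate == rdf_type_iri & d$is_iri &
                     d$object == cls])
}

# transitive containment by iterated loops
oracle_contains_closure <- function(doc) {
  e <- oracle_pairs(doc, "po:contains")
  pairs <- unique(paste(e$s, e$o))
  repeat {
    added <- FALSE
    for (p1 in pairs) {
      a <- strsplit(p1, " ")[[1]]
      for (p2 in pairs) {
        b <- strsplit(p2, " ")[[1]]
        if (a[2] == b[1]) {
          cand <- paste(a[1], b[2])
          if (!cand %in% pairs) {
            pairs <- c(pairs, cand)
            added <- TRUE
          }
        }
      }
    }
    if (!added) break
  }
  do.call(rbind, lapply(pairs, function(p) {
    a <- strsplit(p, " ")[[1]]
    data.frame(ancestor = a[1], descendant = a[2],
               stringsAsFactors = FALSE)
  }))
}

# brute-force enumeration of the replacement-name pattern over all nodes
oracle_replacement <- function(doc) {
  status <- oracle_pairs(doc, "dwciri:taxonomicStatus")
  repl <- expand_curie("openbiodiv:ReplacementName")
  mentions <- oracle_pairs(doc, "pkm:mentions")
  labels <- oracle_lit(doc, "rdfs:label")
  ranks <- oracle_lit(doc, "dwc:verbatimTaxonRank")
  contains <- oracle_pairs(doc, "po:contains")
  noms <- oracle_typed(doc, "openbiodiv:NomenclatureSection")
  lists <- oracle_typed(doc, "openbiodiv:NomenclatureCitationsList")
  tnus <- oracle_typed(doc, "openbiodiv:TaxonomicNameUsage")
  out <- character(0)
  tnu1s <- unique(status$s[status$o == repl])
  for (tnu1 in tnu1s) {
    names1 <- mentions$o[mentions$s == tnu1]
    for (name in names1) {
      if (!name %in% labels$s) next
      rks <- ranks$v[ranks$s == name]
      for (nom in noms) {
        if (!any(contains$s == nom & contains$o == tnu1)) next
        for (cl in lists) {
          if (!any(contains$s == nom & contains$o == cl)) next
          for (cit in contains$o[contains$s == cl]) {
            for (tnu2 in contains$o[contains$s == cit]) {
              if (!tnu2 %in% tnus) next
              for (name2 in mentions$o[mentions$s == tnu2]) {
                if (!name2 %in% labels$s) next
                rks2 <- ranks$v[ranks$s == name2]
                if (length(intersect(rks, rks2)) > 0L) {
                  out <- c(out, paste(name2, name))
                }
              }
            }
          }
        }
      }
    }
  }
  sort(unique(out))
}

# brute-force related-name pattern: ordered pairs of distinct names whose
# usages are (transitively) inside the same nomenclature section
oracle_related <- function(doc) {
  closure <- oracle_contains_closure(doc)
  noms <- oracle_typed(doc, "openbiodiv:NomenclatureSection")
  tnus <- oracle_typed(doc, "openbiodiv:TaxonomicNameUsage")
  mentions <- oracle_pairs(doc, "pkm:mentions")
  out <- character(0)
  for (nom in noms) {
    in_sec <- closure$descendant[closure$ancestor == nom]
    sec_tnus <- intersect(in_sec, tnus)
    sec_names <- unique(mentions$o[mentions$s %in% sec_tnus])
    for (a in sec_names) for (b in sec_names) {
      if (a != b) out <- c(out, paste(b, a))
    }
  }
  sort(unique(out))
}

edges_as_keys <- function(edges) {
  sort(unique(paste(edges$from_name, edges$to_name)))
}

# exhaustive bijection search for graph isomorphism on small graphs
oracle_isomorphic <- function(a, b, renameable = is_instance_iri) {
  da <- tibble::as_tibble(a)
  db <- tibble::as_tibble(b)
  if (nrow(da) != nrow(db)) return(FALSE)
  key <- function(d) {
    sort(paste(d$graph, d$subject, d$predicate, d$object, d$is_iri,
               ifelse(is.na(d$datatype), "-", d$datatype),
               ifelse(is.na(d$lang), "-", d$lang)))
  }
  iris <- function(d) unique(c(d$graph, d$subject, d$object[d$is_iri]))
  va <- iris(da); va <- va[renameable(va)]
  vb <- iris(db); vb <- vb[renameable(vb)]
  if (length(va) != length(vb)) return(FALSE)
  if (length(va) == 0L) return(identical(key(da), key(db)))
  if (length(va) > 8L) stop("oracle only runs on small graphs")
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  for (p in perms(vb)) {
    m <- stats::setNames(p, va)
    d2 <- da
    swap <- function(col, is_iri = NULL) {
      hit <- col %in% names(m)
      if (!is.null(is_iri)) hit <- hit & is_iri
      col[hit] <- unname(m[col[hit]])
      col
    }
    d2$graph <- swap(d2$graph)
    d2$subject <- swap(d2$subject)
    d2$object <- swap(d2$object, d2$is_iri)
    if (identical(key(d2), key(db))) return(TRUE)
  }
  FALSE
}

# random quad document for round-trip property tests
random_doc <- function(n, seed) {
  withr::with_seed(seed, {
    graphs <- paste0("http://openbiodiv.net/", replicate(2, taxograph:::random_uuid()))
    subs <- paste0("http://openbiodiv.net/", replicate(8, taxograph:::random_uuid()))
    preds <- expand_curie(c("rdf:type", "rdfs:label", "pkm:mentions",
                            "po:contains", "dwc:genus", "prism:doi"))
    rows <- lapply(seq_len(n), function(i) {
      p <- sample(preds, 1)
      if (stats::runif(1) < 0.5) {
        dt <- sample(c(NA, expand_curie("xsd:date")), 1)
        val <- if (!is.na(dt)) {
          sprintf("%04d-%02d-%02d", sample(1900:2020, 1),
                  sample(1:12, 1), sample(1:28, 1))
        } else {
          paste0(sample(c(letters, " ", "\"", "\\", "\n", "é"),
                        sample(1:12, 1), replace = TRUE),
                 collapse = "")
        }
        lg <- if (is.na(dt) && stats::runif(1) < 0.3) "en" else NA
        tibble::tibble(graph = sample(graphs, 1), subject = sample(subs, 1),
                       predicate = p, object = val, is_iri = FALSE,
                       datatype = if (is.na(lg)) dt else NA_character_,
                       lang = lg)
      } else {
        tibble::tibble(graph = sample(graphs, 1), subject = sample(subs, 1),
                       predicate = p, object = sample(subs, 1),
                       is_iri = TRUE, datatype = NA_character_,
                       lang = NA_character_)
      }
    })
    rdf_doc(dplyr::bind_rows(rows))
  })
}

python_bin <- function() Sys.which("python")
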