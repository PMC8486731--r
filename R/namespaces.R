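#' Default namespace prefix table
#'
#' The prefix catalogue used throughout the package. It covers the
#' vocabularies of the biodiversity-publishing data model: SPAR ontologies
#' (fabio, doco, deo, datacite, c4o), Darwin Core (dwc, dwciri), Dublin Core
#' (dc, dcterms), PRISM, FOAF, SKOS, the document component pattern ontology
#' (po), the PROTON knowledge-management module (pkm) and the openbiodiv
#' instance/vocabulary namespace.
#'
#' @return A named character vector mapping prefix to namespace IRI.
#' @export
#' @examples
#' rdf_prefixes()[["fabio"]]
rdf_prefixes <- function() {
  c(
    openbiodiv = "http://openbiodiv.net/",
    rdf        = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs       = "http://www.w3.org/2000/01/rdf-schema#",
    foaf       = "http://xmlns.com/foaf/0.1/",
    dc         = "http://purl.org/dc/elements/1.1/",
    dcterms    = "http://purl.org/dc/terms/",
    prism      = "http://prismstandard.org/namespaces/basic/2.0/",
    fabio      = "http://purl.org/spar/fabio/",
    doco       = "http://purl.org/spar/doco/",
    deo        = "http://purl.org/spar/deo/",
    orb        = "http://purl.org/orb/1.0/",
    sro        = "http://salt.semanticauthoring.org/ontologies/sro#",
    po         = "http://www.essepuntato.it/2008/12/pattern#",
    pkm        = "http://proton.semanticweb.org/protonkm#",
    dwc        = "http://rs.tdwg.org/dwc/terms/",
    dwciri     = "http://rs.tdwg.org/dwc/iri/",
    skos       = "http://www.w3.org/2004/02/skos/core#",
    datacite   = "http://purl.org/spar/datacite/",
    c4o        = "http://purl.org/spar/c4o/",
    frbr       = "http://purl.org/vocab/frbr/core#",
    orcid      = "https://orcid.org/",
    xsd        = "http://www.w3.org/2001/XMLSchema#"
  )
}

# An absolute IRI: scheme ':' and something after it, scheme per RFC 3986.
is_absolute_iri <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x) &
    vapply(x, function(s) {
      scheme <- sub(":.*$", "", s)
      # A registered prefix takes priority only in expand_curie(); here we
      # accept anything with a hierarchical or urn-like tail.
      grepl("^[A-Za-z][A-Za-z0-9+.-]*:(//|.+)", s) && nchar(scheme) > 0L
    }, logical(1))
}

#' Expand a CURIE (prefixed name) to an absolute IRI
#'
#' Strings already holding an absolute `http(s)`/`urn` IRI (optionally in
#' angle brackets) pass through unchanged. Otherwise the part before the
#' first `:` must be a registered prefix.
#'
#' @param x Character vector of CURIEs or absolute IRIs.
#' @param namespaces Named character vector of prefix -> namespace IRI.
#' @return Character vector of absolute IRIs.
#' @export
#' @examples
#' expand_curie("fabio:JournalArticle")
#' expand_curie("openbiodiv:Treatment")
expand_curie <- function(x, namespaces = rdf_prefixes()) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    if (grepl("^<.*>$", s)) s <- substr(s, 2L, nchar(s) - 1L)
    if (grepl("^(https?|urn|ftp|mailto|doi)://?", s) || grepl("^urn:", s)) {
      return(s)
    }
    if (!grepl(":", s, fixed = TRUE)) {
      stop("not a CURIE or absolute IRI: '", s, "'", call. = FALSE)
    }
    prefix <- sub(":.*$", "", s)
    local <- sub("^[^:]*:", "", s)
    if (!prefix %in% names(namespaces)) {
      stop("unknown namespace prefix '", prefix, "' in '", s, "'",
           call. = FALSE)
    }
    paste0(namespaces[[prefix]], local)
  }, character(1), USE.NAMES = FALSE)
}

#' Compact an absolute IRI to a CURIE where a registered prefix matches
#'
#' Used by the TriG writer. IRIs whose local part would not be a legal
#' prefixed-name local part are left absolute.
#'
#' @param x Character vector of absolute IRIs.
#' @param namespaces Named character vector of prefix -> namespace IRI.
#' @return Character vector of CURIEs or absolute IRIs.
#' @export
compact_iri <- function(x, namespaces = rdf_prefixes()) {
  # longest namespace first so openbiodiv.net/ does not swallow longer bases
  ns <- namespaces[order(-nchar(namespaces))]
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    for (i in seq_along(ns)) {
      base <- ns[[i]]
      if (startsWith(s, base)) {
        local <- substring(s, nchar(base) + 1L)
        if (grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", local) &&
            !endsWith(local, ".")) {
          return(paste0(names(ns)[i], ":", local))
        }
      }
    }
    s
  }, character(1), USE.NAMES = FALSE)
}
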