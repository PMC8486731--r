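#' Normalize a resource label
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs
#' (spaces, tabs, newlines) to single spaces and applies Unicode NFC.
#' Case is preserved: taxonomic labels are case-significant.
#'
#' @param raw Character vector.
#' @return Normalized character vector.
#' @export
#' @examples
#' normalize_label("  Zelus  casii ")
normalize_label <- function(raw) {
  out <- stringi::stri_trans_nfc(as.character(raw))
  out <- gsub("[\\s\u00a0\u2007\u202f]+", " ", out, perl = TRUE)
  trimws(out)
}

#' Content-addressed digest of a resource key
#'
#' The canonical key is `resource_type:label` (the label already
#' normalized); the digest is the sha256 of its UTF-8 bytes, as 64
#' lowercase hex characters.
#'
#' @param resource_type Short lowercase token, e.g. `"person"`,
#'   `"article"`, `"scientific_name"`. Must not contain `":"`.
#' @param label Normalized label string.
#' @return 64-character lowercase hex string.
#' @export
#' @examples
#' resource_digest("person", "Guanyang Zhang")
resource_digest <- function(resource_type, label) {
  stopifnot(length(resource_type) == 1L, length(label) == 1L)
  if (grepl(":", resource_type, fixed = TRUE)) {
    stop("resource_type must not contain ':'", call. = FALSE)
  }
  key <- paste0(resource_type, ":", label)
  sha256_raw(charToRaw(enc2utf8(key)))
}

format_uuid <- function(hex32) {
  toupper(paste(
    substr(hex32, 1, 8), substr(hex32, 9, 12), substr(hex32, 13, 16),
    substr(hex32, 17, 20), substr(hex32, 21, 32),
    sep = "-"
  ))
}

random_uuid <- function() {
  bytes <- as.integer(floor(stats::runif(16) * 256))
  bytes[7] <- bitwOr(bitwAnd(bytes[7], 0x0F), 0x40)  # version 4
  bytes[9] <- bitwOr(bitwAnd(bytes[9], 0x3F), 0x80)  # RFC 4122 variant
  format_uuid(paste(sprintf("%02x", bytes), collapse = ""))
}

digest_uuid <- function(digest) {
  # name-based UUID derived from the key digest: reproducible mint
  hex <- substr(digest, 1, 32)
  b7 <- strtoi(substr(hex, 13, 14), 16L)
  b9 <- strtoi(substr(hex, 17, 18), 16L)
  b7 <- bitwOr(bitwAnd(b7, 0x0F), 0x40)
  b9 <- bitwOr(bitwAnd(b9, 0x3F), 0x80)
  format_uuid(paste0(substr(hex, 1, 12), sprintf("%02x", b7),
                     substr(hex, 15, 16), sprintf("%02x", b9),
                     substr(hex, 19, 32)))
}

#' Create or open an identifier store
#'
#' The store maps sha256 digests of `type:label` keys to minted IRIs. It
#' lives in memory (an environment) and can persist to a JSON-lines file:
#' one record per line with fields `digest`, `iri`, `resource_type`,
#' `label` and optional `metadata`. Reloading reproduces the map exactly.
#'
#' @param path Optional persistence path; if the file exists it is loaded.
#' @param deterministic If TRUE, minted UUIDs are derived from the key
#'   digest (name-based) instead of drawn at random, so repeated runs
#'   reproduce identical IRIs. Random (v4) UUIDs are the production
#'   default.
#' @param base_iri Namespace under which IRIs are minted.
#' @return An `id_store` object.
#' @export
id_store <- function(path = NULL, deterministic = FALSE,
                     base_iri = "http://openbiodiv.net/") {
  store <- structure(
    list(
      env = new.env(parent = emptyenv()),
      path = path,
      deterministic = deterministic,
      base_iri = base_iri,
      counters = new.env(parent = emptyenv())
    ),
    class = "id_store"
  )
  assign("minted", 0L, envir = store$counters)
  assign("reused", 0L, envir = store$counters)
  if (!is.null(path) && file.exists(path)) {
    id_store_load(store, path)
  }
  store
}

#' @export
print.id_store <- function(x, ...) {
  cat("<id_store> ", length(ls(x$env)), " records",
      if (x$deterministic) " (deterministic minting)" else "",
      if (!is.null(x$path)) paste0("; path: ", x$path) else "",
      "\n", sep = "")
  invisible(x)
}

id_store_size <- function(store) length(ls(store$env))

id_store_counters <- function(store) {
  list(minted = get("minted", envir = store$counters),
       reused = get("reused", envir = store$counters))
}

id_store_reset_counters <- function(store) {
  assign("minted", 0L, envir = store$counters)
  assign("reused", 0L, envir = store$counters)
  invisible(store)
}

#' Look up or mint an IRI for a typed, labelled resource
#'
#' Idempotent content-addressed minting: if the digest of
#' `resource_type:label` is already present the stored IRI is returned
#' and the store is untouched; otherwise a fresh
#' `http://openbiodiv.net/<UUID>` IRI is minted, recorded (and persisted
#' when the store has a path) and returned.
#'
#' @param store An [id_store()].
#' @param resource_type Resource type token.
#' @param label Raw label (normalized internally).
#' @param metadata Optional named list of strings (e.g. DOI) kept with the
#'   record.
#' @return The IRI string.
#' @export
get_or_mint <- function(store, resource_type, label, metadata = NULL) {
  label <- normalize_label(label)
  if (!nzchar(label)) {
    stop("cannot mint an identifier for an empty label (type '",
         resource_type, "')", call. = FALSE)
  }
  digest <- resource_digest(resource_type, label)
  if (exists(digest, envir = store$env, inherits = FALSE)) {
    assign("reused", get("reused", envir = store$counters) + 1L,
           envir = store$counters)
    return(get(digest, envir = store$env)$iri)
  }
  uuid <- if (store$deterministic) digest_uuid(digest) else random_uuid()
  record <- list(
    digest = digest,
    iri = paste0(store$base_iri, uuid),
    resource_type = resource_type,
    label = label,
    metadata = metadata
  )
  assign(digest, record, envir = store$env)
  assign("minted", get("minted", envir = store$counters) + 1L,
         envir = store$counters)
  if (!is.null(store$path)) {
    cat(jsonlite::toJSON(record, auto_unbox = TRUE), "\n",
        file = store$path, append = TRUE, sep = "")
  }
  record$iri
}

#' Preload a record with a known IRI
#'
#' Registers an externally assigned identifier (for example one published
#' previously) so that subsequent [get_or_mint()] calls resolve to it.
#'
#' @inheritParams get_or_mint
#' @param iri The IRI to associate with the key.
#' @return The IRI, invisibly.
#' @export
id_store_put <- function(store, resource_type, label, iri, metadata = NULL) {
  label <- normalize_label(label)
  digest <- resource_digest(resource_type, label)
  record <- list(digest = digest, iri = iri, resource_type = resource_type,
                 label = label, metadata = metadata)
  assign(digest, record, envir = store$env)
  if (!is.null(store$path)) {
    cat(jsonlite::toJSON(record, auto_unbox = TRUE), "\n",
        file = store$path, append = TRUE, sep = "")
  }
  invisible(iri)
}

#' Persist / reload an identifier store
#'
#' `id_store_save()` rewrites the whole store as JSON-lines;
#' `id_store_load()` replaces the in-memory map with the file contents
#' (later lines win, so append-logs replay correctly).
#'
#' @param store An [id_store()].
#' @param path File path; defaults to the store's own path.
#' @return The store, invisibly.
#' @export
id_store_save <- function(store, path = store$path) {
  stopifnot(!is.null(path))
  digests <- ls(store$env)
  lines <- vapply(digests, function(d) {
    as.character(jsonlite::toJSON(get(d, envir = store$env),
                                  auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(store)
}

#' @rdname id_store_save
#' @export
id_store_load <- function(store, path = store$path) {
  stopifnot(!is.null(path), file.exists(path))
  rm(list = ls(store$env), envir = store$env)
  for (line in readLines(path, encoding = "UTF-8", warn = FALSE)) {
    if (!nzchar(trimws(line))) next
    record <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    assign(record$digest, record, envir = store$env)
  }
  invisible(store)
}

#' Export the store as a tibble
#'
#' @param store An [id_store()].
#' @return A tibble with digest, iri, resource_type and label columns.
#' @export
id_store_records <- function(store) {
  digests <- ls(store$env)
  purrr::map_dfr(digests, function(d) {
    r <- get(d, envir = store$env)
    tibble::tibble(digest = r$digest, iri = r$iri,
                   resource_type = r$resource_type, label = r$label)
  })
}

#' Suffixed IRI for a backbone-taxonomy resource
#'
#' Backbone resources are not content-addressed: their IRIs are the
#' import run's base UUID plus the row's local integer id, with a suffix
#' distinguishing the concept itself (no suffix), its scientific name
#' (`-scName`) and its concept label (`-label`).
#'
#' @param base_uuid UUID string shared by one backbone version.
#' @param local_id Non-negative integer id of the row.
#' @param kind `"concept"`, `"scientific_name"` or `"concept_label"`.
#' @param base_iri Namespace.
#' @return The IRI string.
#' @export
#' @examples
#' gbif_iri("F1DD0CF0-217D-422B-BAA4-58901976D7B4", 4239, "concept")
gbif_iri <- function(base_uuid, local_id,
                     kind = c("concept", "scientific_name", "concept_label"),
                     base_iri = "http://openbiodiv.net/") {
  kind <- match.arg(kind)
  local_id <- as.integer(local_id)
  stopifnot(!is.na(local_id), local_id >= 0L)
  stem <- paste0(base_iri, base_uuid, "-", local_id)
  switch(kind,
    concept = stem,
    scientific_name = paste0(stem, "-scName"),
    concept_label = paste0(stem, "-label")
  )
}
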