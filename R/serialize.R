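escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      ch <- chars[[j]]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[[j + 1L]]
        buf <- c(buf, switch(nxt,
          "n" = "\n", "r" = "\r", "t" = "\t",
          "\"" = "\"", "\\" = "\\",
          stop("unknown escape \\", nxt, call. = FALSE)
        ))
        j <- j + 2L
      } else {
        buf <- c(buf, ch)
        j <- j + 1L
      }
    }
    out[[i]] <- paste0(buf, collapse = "")
  }
  out
}

term_out <- function(x, is_iri, datatype, lang, ns, compact = TRUE) {
  if (is_iri) {
    c <- if (compact) compact_iri(x, ns) else x
    if (identical(c, x)) paste0("<", x, ">") else c
  } else {
    base <- paste0("\"", escape_literal(x), "\"")
    if (!is.na(lang)) {
      paste0(base, "@", lang)
    } else if (!is.na(datatype)) {
      cdt <- if (compact) compact_iri(datatype, ns) else datatype
      if (identical(cdt, datatype)) {
        paste0(base, "^^<", datatype, ">")
      } else {
        paste0(base, "^^", cdt)
      }
    } else {
      base
    }
  }
}

#' Serialize a quad document
#'
#' TriG output groups quads by named graph into `<graph> { ... }` blocks
#' with a `@prefix` header; N-Quads output is one flat
#' `<s> <p> o <g> .` statement per line. Both round-trip through
#' [rdf_parse()] to the identical quad set.
#'
#' @param doc A `triple_doc`.
#' @param format `"trig"` or `"nquads"`.
#' @return A single string.
#' @export
rdf_serialize <- function(doc, format = c("trig", "nquads")) {
  format <- match.arg(format)
  d <- tibble::as_tibble(doc)
  ns <- doc_namespaces(doc)
  if (format == "nquads") {
    if (nrow(d) == 0L) return("")
    lines <- vapply(seq_len(nrow(d)), function(i) {
      paste(
        paste0("<", d$subject[i], ">"),
        paste0("<", d$predicate[i], ">"),
        term_out(d$object[i], d$is_iri[i], d$datatype[i], d$lang[i], ns,
                 compact = FALSE),
        paste0("<", d$graph[i], ">"),
        "."
      )
    }, character(1))
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  header <- paste0("@prefix ", names(ns), ": <", unname(ns), "> .")
  blocks <- character(0)
  d <- dplyr::arrange(d, .data$graph, .data$subject, .data$predicate,
                      .data$object)
  for (g in unique(d$graph)) {
    dg <- d[d$graph == g, ]
    stmts <- vapply(seq_len(nrow(dg)), function(i) {
      paste0("    ",
             term_out(dg$subject[i], TRUE, NA, NA, ns), " ",
             term_out(dg$predicate[i], TRUE, NA, NA, ns), " ",
             term_out(dg$object[i], dg$is_iri[i], dg$datatype[i],
                      dg$lang[i], ns),
             " .")
    }, character(1))
    blocks <- c(blocks,
                paste0(term_out(g, TRUE, NA, NA, ns), " {"),
                stmts, "}", "")
  }
  paste0(paste(c(header, "", blocks), collapse = "\n"), "\n")
}

# --- tokenizer ---------------------------------------------------------------

trig_tokenize <- function(text) {
  tokens <- list()
  line <- 1L
  i <- 1L
  n <- nchar(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  push <- function(type, value) {
    tokens[[length(tokens) + 1L]] <<- list(type = type, value = value,
                                           line = line)
  }
  while (i <= n) {
    ch <- chars[[i]]
    if (ch == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (ch %in% c(" ", "\t", "\r")) { i <- i + 1L; next }
    if (ch == "#") {
      while (i <= n && chars[[i]] != "\n") i <- i + 1L
      next
    }
    if (ch == "<") {
      j <- i + 1L
      while (j <= n && chars[[j]] != ">") {
        if (chars[[j]] == "\n") {
          stop("TriG parse error at line ", line, ": unterminated IRI",
               call. = FALSE)
        }
        j <- j + 1L
      }
      if (j > n) stop("TriG parse error at line ", line,
                      ": unterminated IRI", call. = FALSE)
      push("iri", paste0(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + 1L
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      buf <- character(0)
      repeat {
        if (j > n) stop("TriG parse error at line ", line,
                        ": unterminated literal", call. = FALSE)
        cj <- chars[[j]]
        if (cj == "\\") {
          buf <- c(buf, cj, chars[[j + 1L]])
          j <- j + 2L
        } else if (cj == "\"") {
          break
        } else {
          if (cj == "\n") line <- line + 1L
          buf <- c(buf, cj)
          j <- j + 1L
        }
      }
      push("literal", unescape_literal(paste0(buf, collapse = "")))
      i <- j + 1L
      next
    }
    if (ch %in% c("{", "}", ".", ";", ",")) {
      push(ch, ch)
      i <- i + 1L
      next
    }
    if (ch == "^" && i < n && chars[[i + 1L]] == "^") {
      push("^^", "^^")
      i <- i + 2L
      next
    }
    if (ch == "@") {
      j <- i + 1L
      while (j <= n && grepl("[A-Za-z-]", chars[[j]])) j <- j + 1L
      word <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      if (word == "prefix") push("@prefix", word) else push("lang", word)
      i <- j
      next
    }
    # bare word: prefixed name, 'a', 'GRAPH', boolean
    j <- i
    while (j <= n && !chars[[j]] %in%
           c(" ", "\t", "\r", "\n", "{", "}", ";", ",", "\"", "<")) {
      # a terminating '.' (followed by whitespace/EOF) ends the word
      if (chars[[j]] == "." &&
          (j == n || chars[[j + 1L]] %in% c(" ", "\t", "\r", "\n"))) break
      j <- j + 1L
    }
    word <- paste0(chars[i:(j - 1L)], collapse = "")
    if (word == "") stop("TriG parse error at line ", line,
                         ": unexpected character '", ch, "'", call. = FALSE)
    push("word", word)
    i <- j
    next
  }
  tokens
}

resolve_term <- function(tok, ns) {
  if (tok$type == "iri") return(tok$value)
  if (tok$type == "word") {
    if (tok$value == "a") {
      return(paste0(ns[["rdf"]], "type"))
    }
    prefix <- sub(":.*$", "", tok$value)
    if (!prefix %in% names(ns)) {
      stop("TriG parse error at line ", tok$line,
           ": unknown prefix '", prefix, "'", call. = FALSE)
    }
    return(paste0(ns[[prefix]], sub("^[^:]*:", "", tok$value)))
  }
  stop("TriG parse error at line ", tok$line, ": expected IRI, got ",
       tok$type, call. = FALSE)
}

#' Parse TriG or N-Quads text into a quad document
#'
#' Supports the subset of TriG this package emits plus common hand-written
#' forms: `@prefix` declarations, optional `GRAPH` keyword, `;` predicate
#' lists, `,` object lists, language tags and datatyped literals. Blank
#' nodes are deliberately unsupported (the data model mints an IRI for
#' every resource). Syntax errors report the line number.
#'
#' @param text A TriG or N-Quads string.
#' @param format `"trig"` or `"nquads"` (N-Quads is parsed by the same
#'   grammar: a graph IRI after the object).
#' @param namespaces Starting prefix table; `@prefix` lines extend it.
#' @return A `triple_doc`.
#' @export
rdf_parse <- function(text, format = c("trig", "nquads"),
                      namespaces = rdf_prefixes()) {
  format <- match.arg(format)
  ns <- namespaces
  toks <- trig_tokenize(text)
  rows <- list()
  emit <- function(g, s, p, o) rows[[length(rows) + 1L]] <<- c(list(g = g, s = s, p = p), o)
  k <- 1L
  npeek <- function(offset = 0L) {
    if (k + offset <= length(toks)) toks[[k + offset]] else NULL
  }
  expect <- function(type) {
    t <- npeek()
    if (is.null(t) || t$type != type) {
      stop("TriG parse error at line ",
           if (is.null(t)) "EOF" else t$line,
           ": expected '", type, "'", call. = FALSE)
    }
    k <<- k + 1L
    t
  }
  read_object <- function() {
    t <- npeek()
    if (is.null(t)) stop("TriG parse error: unexpected EOF", call. = FALSE)
    if (t$type == "literal") {
      k <<- k + 1L
      dt <- NA_character_; lg <- NA_character_
      t2 <- npeek()
      if (!is.null(t2) && t2$type == "^^") {
        k <<- k + 1L
        dt <- resolve_term(npeek(), ns)
        k <<- k + 1L
      } else if (!is.null(t2) && t2$type == "lang") {
        k <<- k + 1L
        lg <- t2$value
      }
      list(o = t$value, is_iri = FALSE, datatype = dt, lang = lg)
    } else {
      v <- resolve_term(t, ns)
      k <<- k + 1L
      list(o = v, is_iri = TRUE, datatype = NA_character_, lang = NA_character_)
    }
  }
  read_triples_into <- function(graph_iri) {
    # subject (predicate object (, object)* (; predicate object ...)*)? .
    repeat {
      t <- npeek()
      if (is.null(t) || t$type == "}") return()
      subj <- resolve_term(t, ns)
      k <<- k + 1L
      repeat {
        pred <- resolve_term(npeek(), ns)
        k <<- k + 1L
        repeat {
          o <- read_object()
          if (format == "nquads" || is.null(graph_iri)) {
            gtok <- npeek()
            g <- resolve_term(gtok, ns)
            k <<- k + 1L
            emit(g, subj, pred, o)
          } else {
            emit(graph_iri, subj, pred, o)
          }
          t2 <- npeek()
          if (!is.null(t2) && t2$type == ",") { k <<- k + 1L; next }
          break
        }
        t2 <- npeek()
        if (!is.null(t2) && t2$type == ";") {
          k <<- k + 1L
          # tolerate trailing ';' before '.'
          t3 <- npeek()
          if (!is.null(t3) && t3$type %in% c(".", "}")) break
          next
        }
        break
      }
      t2 <- npeek()
      if (!is.null(t2) && t2$type == ".") k <<- k + 1L
    }
  }
  while (k <= length(toks)) {
    t <- npeek()
    if (t$type == "@prefix") {
      k <- k + 1L
      ptok <- expect("word")
      itok <- expect("iri")
      expect(".")
      pname <- sub(":$", "", ptok$value)
      ns[[pname]] <- itok$value
      next
    }
    if (t$type == "word" && toupper(t$value) == "GRAPH") {
      k <- k + 1L
      t <- npeek()
    }
    if (format == "nquads") {
      read_triples_into(NULL)
      next
    }
    # graph block: <iri> { ... }
    graph_iri <- resolve_term(t, ns)
    k <- k + 1L
    expect("{")
    read_triples_into(graph_iri)
    expect("}")
    # optional '.' after block
    t2 <- npeek()
    if (!is.null(t2) && t2$type == ".") k <- k + 1L
  }
  if (length(rows) == 0L) return(rdf_doc(namespaces = ns))
  q <- tibble::tibble(
    graph = vapply(rows, `[[`, character(1), "g"),
    subject = vapply(rows, `[[`, character(1), "s"),
    predicate = vapply(rows, `[[`, character(1), "p"),
    object = vapply(rows, `[[`, character(1), "o"),
    is_iri = vapply(rows, `[[`, logical(1), "is_iri"),
    datatype = vapply(rows, `[[`, character(1), "datatype"),
    lang = vapply(rows, `[[`, character(1), "lang")
  )
  rdf_doc(q, namespaces = ns)
}

#' Read / write helpers for TriG files
#'
#' @param doc A `triple_doc`.
#' @param path File path.
#' @return `write_trig()` returns `path` invisibly; `read_trig()` a
#'   `triple_doc`.
#' @export
write_trig <- function(doc, path) {
  writeLines(rdf_serialize(doc, "trig"), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_trig
#' @export
read_trig <- function(path) {
  rdf_parse(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                  collapse = "\n"), "trig")
}
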