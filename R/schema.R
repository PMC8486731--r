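#' Load an extraction schema
#'
#' Schemas are declarative JSON documents (shipped under
#' `inst/extdata/schemas/`) describing, per node type, the relative XPath
#' location, the atoms (text fields) to pull out, the constructor to
#' dispatch to and the child node types to recurse into. A JSON Schema for
#' the format lives next to them (`extraction-schema.schema.json`) and
#' [validate_schema_spec()] enforces it structurally.
#'
#' @param dialect `"taxpub"`, `"taxonx"`, or a path to a schema JSON file.
#' @return A validated schema list.
#' @export
load_schema <- function(dialect) {
  path <- if (file.exists(dialect)) {
    dialect
  } else {
    system.file("extdata", "schemas",
                paste0(tolower(dialect), ".json"),
                package = "taxograph", mustWork = TRUE)
  }
  schema <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
  validate_schema_spec(schema)
  schema
}

#' Validate an extraction schema against the format contract
#'
#' Checks the structural constraints published in
#' `extraction-schema.schema.json`: required fields, legal `value_kind`
#' and `semantic_kind` values, that every child reference and the root
#' resolve to a defined node, that constructors resolve to registered
#' constructor functions, and that child references contain no cycle.
#'
#' @param schema A schema list as returned by [jsonlite::fromJSON()].
#' @return TRUE invisibly; errors describe the first violation found.
#' @export
validate_schema_spec <- function(schema) {
  need <- function(cond, ...) if (!cond) stop("schema: ", ..., call. = FALSE)
  need(all(c("dialect", "root", "nodes", "coverage") %in% names(schema)),
       "missing one of dialect/root/nodes/coverage")
  need(schema$dialect %in% c("TaxPub", "TaxonX"),
       "dialect must be TaxPub or TaxonX")
  need(schema$root %in% names(schema$nodes),
       "root node '", schema$root, "' is not defined")
  known_constructors <- names(constructor_registry())
  for (nm in names(schema$nodes)) {
    node <- schema$nodes[[nm]]
    need(all(c("resource_type", "location", "constructor", "atoms",
               "children") %in% names(node)),
         "node '", nm, "' missing required fields")
    need(node$constructor %in% known_constructors,
         "node '", nm, "' uses unknown constructor '", node$constructor, "'")
    for (at in names(node$atoms)) {
      atom <- node$atoms[[at]]
      need(all(c("location", "value_kind", "semantic_kind") %in%
                 names(atom)),
           "atom '", at, "' of node '", nm, "' incomplete")
      need(atom$value_kind %in% c("element-text", "attribute"),
           "atom '", at, "' of '", nm, "': bad value_kind")
      need(atom$semantic_kind %in%
             c("string", "link", "date", "integer", "identifier"),
           "atom '", at, "' of '", nm, "': bad semantic_kind")
    }
    for (ch in node$children) {
      need(ch %in% names(schema$nodes),
           "node '", nm, "' references undefined child '", ch, "'")
    }
  }
  # cycle check over child references
  visiting <- character(0)
  visited <- character(0)
  visit <- function(nm) {
    if (nm %in% visited) return(invisible(NULL))
    if (nm %in% visiting) stop("schema: cyclic child reference through '",
                               nm, "'", call. = FALSE)
    visiting <<- c(visiting, nm)
    for (ch in schema$nodes[[nm]]$children) visit(ch)
    visiting <<- setdiff(visiting, nm)
    visited <<- c(visited, nm)
  }
  visit(schema$root)
  invisible(TRUE)
}
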