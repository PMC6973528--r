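# Declarative mapping documents: a YAML subset of R2RML covering subject IRI
# templates, constant predicates, column-valued objects with datatypes, and
# named value transforms. The document shipped under extdata/ maps the
# fixture bundle's five tables onto the linkage ontology.

parse_po_entry <- function(entry, codebooks) {
  transform <- NULL
  if (!is.null(entry$transform)) {
    tr <- entry$transform
    if (identical(tr$kind, "decode")) {
      cb <- codebooks[[tr$codebook]]
      if (is.null(cb)) {
        stop("mapping references unknown codebook: ", tr$codebook,
             call. = FALSE)
      }
      transform <- list(kind = "decode", codebook = unlist(cb),
                        unmapped = tr$unmapped %||% "error")
    } else if (identical(tr$kind, "date")) {
      transform <- list(kind = "date",
                        pattern = tr$pattern %||% "dd-MM-yyyy")
    } else {
      stop("unknown transform kind in mapping: ", tr$kind, call. = FALSE)
    }
  }
  kind <- entry$kind %||% "literal"
  list(predicate = entry$predicate,
       object = term_template(entry$template, term_kind = kind,
                              datatype = entry$datatype %||% "xsd:string",
                              transform = transform))
}

#' Read a declarative mapping document
#'
#' The document is YAML with an optional `codebooks` section (named
#' code-to-label tables) and a `mappings` list; each mapping names its
#' `source` table, a `subject` IRI template, optional `types` (classes
#' asserted via `rdf:type`) and `predicate_objects` entries carrying a
#' `predicate`, an object `template`, and optionally `kind` (`iri` or
#' `literal`), `datatype`, and a `transform`
#' (`{kind: date, pattern: dd-MM-yyyy}` or
#' `{kind: decode, codebook: <name>}`).
#'
#' @param path Path to the YAML mapping document.
#' @return List of [triples_map()] objects.
#' @export
read_mapping <- function(path) {
  doc <- yaml::read_yaml(path)
  codebooks <- doc$codebooks %||% list()
  lapply(doc$mappings, function(m) {
    triples_map(
      source = m$source,
      subject = term_template(m$subject, term_kind = "iri"),
      types = unlist(m$types) %||% character(0),
      predicate_objects = lapply(m$predicate_objects, parse_po_entry,
                                 codebooks = codebooks))
  })
}

#' The default mapping document for the fixture bundle
#'
#' @return List of [triples_map()] objects covering the `patients`,
#'   `stations`, `regions`, `observations` and `weekly_counts` tables.
#' @export
default_mapping <- function() {
  read_mapping(system.file("extdata", "mapping.yaml",
                           package = "triplelink", mustWork = TRUE))
}
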