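# In-memory typed triple graph: IRIs, typed literals, pattern matching and
# N-Triples persistence. Triples are held in a data.frame with set semantics;
# every API that returns a sequence returns it in a deterministic sorted order.

#' Default namespace prefix table
#'
#' Prefixes used throughout the linkage ontology: the project namespace
#' (`avert:`), GeoSPARQL (`geo:`), XML Schema datatypes (`xsd:`), FOAF
#' (`foaf:`), core RDF/RDFS and PROV.
#'
#' @return Named character vector mapping prefix to namespace IRI.
#' @export
#' @examples
#' tl_prefixes()[["xsd"]]
tl_prefixes <- function() {
  c(
    rdf   = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
    rdfs  = "http://www.w3.org/2000/01/rdf-schema#",
    xsd   = "http://www.w3.org/2001/XMLSchema#",
    foaf  = "http://xmlns.com/foaf/0.1/",
    geo   = "http://www.opengis.net/ont/geosparql#",
    prov  = "http://www.w3.org/ns/prov#",
    avert = "http://data.avert.ie/avert#"
  )
}

#' Expand a compact IRI (CURIE) against a prefix table
#'
#' Strings that already look like absolute IRIs are returned unchanged;
#' `prefix:local` forms are expanded when the prefix is known.
#'
#' @param x Character vector of CURIEs or absolute IRIs.
#' @param namespaces Named character vector (see [tl_prefixes()]).
#' @return Character vector of absolute IRIs.
#' @export
#' @examples
#' expand_curie("avert:Patient")
expand_curie <- function(x, namespaces = tl_prefixes()) {
  vapply(x, function(s) {
    if (grepl("^[A-Za-z][A-Za-z0-9+.-]*://", s)) return(s)
    m <- regmatches(s, regexec("^([A-Za-z][A-Za-z0-9._-]*):(.*)$", s))[[1]]
    if (length(m) == 3L && m[2] %in% names(namespaces)) {
      return(paste0(namespaces[[m[2]]], m[3]))
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

is_absolute_iri <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x) & !grepl("[[:space:]<>\"]", x) &
    nchar(x) > 0L
}

#' Construct an IRI term
#'
#' @param value Absolute IRI string (or CURIE, expanded against
#'   `namespaces`). Must contain no unencoded whitespace.
#' @param namespaces Prefix table for CURIE expansion.
#' @return A term object of kind `"iri"`.
#' @export
#' @examples
#' iri("http://data.avert.ie/patient/1")
#' iri("avert:WeatherStation")
iri <- function(value, namespaces = tl_prefixes()) {
  stopifnot(is.character(value), length(value) == 1L)
  value <- expand_curie(value, namespaces)
  if (!is_absolute_iri(value)) {
    stop("invalid IRI: ", dQuote(value),
         " (must be absolute, with no unencoded whitespace)", call. = FALSE)
  }
  structure(list(kind = "iri", value = value), class = "tl_term")
}

# lexical validity per datatype; unknown datatypes are accepted as-is
validate_lexical <- function(lexical, datatype) {
  local <- sub("^.*[#/]", "", datatype)
  ok <- switch(local,
    date = grepl("^\\d{4}-\\d{2}-\\d{2}$", lexical) &&
      !is.na(as.Date(lexical, format = "%Y-%m-%d", optional = TRUE)) &&
      format(as.Date(lexical), "%Y-%m-%d") == lexical,
    dateTime = !is.na(as.POSIXct(sub("Z$", "", lexical),
                                 format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")),
    double = , decimal = , float = suppressWarnings(!is.na(as.numeric(lexical))),
    integer = , int = , long = grepl("^[+-]?\\d+$", lexical),
    boolean = lexical %in% c("true", "false", "0", "1"),
    TRUE
  )
  isTRUE(ok)
}

#' Construct a typed literal term
#'
#' Literal equality is (lexical form, datatype) pair equality: no value-space
#' canonicalisation is performed, so `"1.0"` and `"1.00"` are distinct terms.
#'
#' @param lexical Lexical form (character scalar).
#' @param datatype Datatype IRI or CURIE (default `xsd:string`).
#' @param namespaces Prefix table for CURIE expansion.
#' @return A term object of kind `"literal"`.
#' @export
#' @examples
#' typed_literal("1985-10-20", "xsd:date")
typed_literal <- function(lexical, datatype = "xsd:string",
                          namespaces = tl_prefixes()) {
  stopifnot(is.character(lexical), length(lexical) == 1L, !is.na(lexical))
  dt <- iri(datatype, namespaces)$value
  if (!validate_lexical(lexical, dt)) {
    stop("lexical form ", dQuote(lexical), " is not valid for datatype <",
         dt, ">", call. = FALSE)
  }
  structure(list(kind = "literal", lexical = lexical, datatype = dt),
            class = "tl_term")
}

#' @export
print.tl_term <- function(x, ...) {
  cat(term_encode_obj(x), "\n")
  invisible(x)
}

# --- N-Triples term encoding (also the internal binding representation) -----

escape_nt <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

unescape_nt <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[i]
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    buf <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      ch <- chars[j]
      if (ch == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        rep <- switch(nxt, n = "\n", r = "\r", t = "\t",
                      "\\" = "\\", "\"" = "\"", NULL)
        if (!is.null(rep)) {
          buf <- c(buf, rep)
          j <- j + 2L
          next
        }
      }
      buf <- c(buf, ch)
      j <- j + 1L
    }
    out[i] <- paste(buf, collapse = "")
  }
  out
}

term_encode_obj <- function(term) {
  if (term$kind == "iri") paste0("<", term$value, ">")
  else paste0("\"", escape_nt(term$lexical), "\"^^<", term$datatype, ">")
}

# vectorised encode from graph columns
term_encode <- function(object, object_kind, datatype) {
  if (length(object) == 0L) return(character(0))
  ifelse(object_kind == "iri",
         paste0("<", object, ">"),
         paste0("\"", escape_nt(object), "\"^^<", datatype, ">"))
}

#' Decode an encoded term string back to a term object
#'
#' Pattern-match results ([match_pattern()], [evaluate_query()]) carry terms
#' in their N-Triples encoding (`<iri>` or `"lexical"^^<datatype>`); this
#' inverts that encoding.
#'
#' @param x Encoded term string.
#' @return A term object (see [iri()], [typed_literal()]).
#' @export
term_decode <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("^<.*>$", x)) {
    iri(substr(x, 2L, nchar(x) - 1L))
  } else {
    m <- regmatches(x, regexec('^"(.*)"\\^\\^<([^>]*)>$', x))[[1]]
    if (length(m) != 3L) stop("malformed encoded term: ", x, call. = FALSE)
    typed_literal(unescape_nt(m[2]), m[3])
  }
}

#' Lexical form (or IRI string) of an encoded term
#' @param x Character vector of encoded terms.
#' @return Character vector of lexical forms / IRI strings.
#' @export
term_value <- function(x) {
  vapply(x, function(t) {
    d <- term_decode(t)
    if (d$kind == "iri") d$value else d$lexical
  }, character(1), USE.NAMES = FALSE)
}

# --- graph ------------------------------------------------------------------

empty_triple_frame <- function() {
  data.frame(subject = character(0), predicate = character(0),
             object = character(0), object_kind = character(0),
             datatype = character(0), stringsAsFactors = FALSE)
}

#' Create an empty triple graph
#'
#' The graph stores subject-predicate-object triples with typed literals,
#' under set semantics: re-adding an existing triple leaves the graph
#' unchanged.
#'
#' @param namespaces Named character vector of prefix bindings.
#' @return An object of class `triple_graph`.
#' @export
#' @examples
#' g <- triple_graph()
#' g <- add_triple(g, "avert:p1", "rdf:type", "avert:Patient")
#' graph_size(g)
triple_graph <- function(namespaces = tl_prefixes()) {
  if (anyDuplicated(names(namespaces))) {
    stop("namespace prefixes must be unique", call. = FALSE)
  }
  structure(list(triples = empty_triple_frame(), namespaces = namespaces),
            class = "triple_graph")
}

#' Number of triples in a graph
#' @param graph A `triple_graph`.
#' @return Integer count.
#' @export
graph_size <- function(graph) {
  stopifnot(inherits(graph, "triple_graph"))
  nrow(graph$triples)
}

triple_keys <- function(tr) {
  paste(tr$subject, tr$predicate, tr$object_kind, tr$object,
        ifelse(is.na(tr$datatype), "", tr$datatype), sep = "\r")
}

resolve_node <- function(x, namespaces, position) {
  if (inherits(x, "tl_term")) {
    if (x$kind != "iri") {
      stop(position, " must be an IRI term", call. = FALSE)
    }
    return(x$value)
  }
  if (is.character(x) && length(x) == 1L) return(iri(x, namespaces)$value)
  stop("malformed term in ", position, " position", call. = FALSE)
}

resolve_object <- function(x, namespaces) {
  if (inherits(x, "tl_term")) return(x)
  if (is.character(x) && length(x) == 1L) return(iri(x, namespaces))
  stop("malformed term in object position", call. = FALSE)
}

#' Add one triple to a graph
#'
#' @param graph A `triple_graph`.
#' @param subject,predicate IRI term, absolute IRI string or CURIE.
#' @param object IRI (as for `subject`) or a [typed_literal()].
#' @return The graph with the triple present exactly once.
#' @export
add_triple <- function(graph, subject, predicate, object) {
  stopifnot(inherits(graph, "triple_graph"))
  ns <- graph$namespaces
  s <- resolve_node(subject, ns, "subject")
  p <- resolve_node(predicate, ns, "predicate")
  o <- resolve_object(object, ns)
  row <- data.frame(
    subject = s, predicate = p,
    object = if (o$kind == "iri") o$value else o$lexical,
    object_kind = o$kind,
    datatype = if (o$kind == "iri") NA_character_ else o$datatype,
    stringsAsFactors = FALSE
  )
  add_triple_rows(graph, row)
}

# bulk insert of pre-validated rows, enforcing set semantics
add_triple_rows <- function(graph, rows) {
  if (nrow(rows) == 0L) return(graph)
  combined <- rbind(graph$triples, rows)
  graph$triples <- combined[!duplicated(triple_keys(combined)), , drop = FALSE]
  rownames(graph$triples) <- NULL
  graph
}

#' Test whether a fully concrete triple is present
#' @inheritParams add_triple
#' @return Logical scalar.
#' @export
graph_contains <- function(graph, subject, predicate, object) {
  ns <- graph$namespaces
  s <- resolve_node(subject, ns, "subject")
  p <- resolve_node(predicate, ns, "predicate")
  o <- resolve_object(object, ns)
  key <- paste(s, p, o$kind,
               if (o$kind == "iri") o$value else o$lexical,
               if (o$kind == "iri") "" else o$datatype, sep = "\r")
  key %in% triple_keys(graph$triples)
}

#' Merge two graphs (set union of their triples)
#' @param a,b `triple_graph` objects.
#' @return A `triple_graph` with `a`'s namespaces.
#' @export
graph_union <- function(a, b) {
  stopifnot(inherits(a, "triple_graph"), inherits(b, "triple_graph"))
  add_triple_rows(a, b$triples)
}

#' Set equality of two graphs (term-level)
#' @param a,b `triple_graph` objects.
#' @return Logical scalar.
#' @export
graphs_equal <- function(a, b) {
  setequal(triple_keys(a$triples), triple_keys(b$triples))
}

#' @export
print.triple_graph <- function(x, ...) {
  cat("<triple_graph> ", graph_size(x), " triples, ",
      length(x$namespaces), " namespaces\n", sep = "")
  invisible(x)
}

# --- pattern matching -------------------------------------------------------

is_var <- function(x) is.character(x) && length(x) == 1L && startsWith(x, "?")

#' Match a triple pattern against a graph
#'
#' Each position is either a concrete term (IRI/CURIE string, term object)
#' or a variable written `"?name"`. Returns one row per matching triple,
#' with one column per distinct variable; values are N-Triples-encoded
#' terms (decode with [term_decode()] / [term_value()]). Rows are sorted by
#' the matched triple's (subject, predicate, object) encoding so results
#' are deterministic.
#'
#' @param graph A `triple_graph`.
#' @param subject,predicate,object Concrete term or `"?var"`.
#' @return A data.frame of bindings (zero columns if no variables).
#' @export
#' @examples
#' g <- add_triple(triple_graph(), "avert:p1", "rdf:type", "avert:Patient")
#' match_pattern(g, "?s", "rdf:type", "avert:Patient")
match_pattern <- function(graph, subject = "?s", predicate = "?p",
                          object = "?o") {
  stopifnot(inherits(graph, "triple_graph"))
  tr <- graph$triples
  ns <- graph$namespaces
  keep <- rep(TRUE, nrow(tr))
  if (!is_var(subject)) {
    keep <- keep & tr$subject == resolve_node(subject, ns, "subject")
  }
  if (!is_var(predicate)) {
    keep <- keep & tr$predicate == resolve_node(predicate, ns, "predicate")
  }
  if (!is_var(object)) {
    o <- resolve_object(object, ns)
    if (o$kind == "iri") {
      keep <- keep & tr$object_kind == "iri" & tr$object == o$value
    } else {
      keep <- keep & tr$object_kind == "literal" & tr$object == o$lexical &
        tr$datatype == o$datatype
    }
  }
  tr <- tr[keep, , drop = FALSE]
  n_hit <- nrow(tr)
  enc_s <- if (n_hit == 0L) character(0) else paste0("<", tr$subject, ">")
  enc_p <- if (n_hit == 0L) character(0) else paste0("<", tr$predicate, ">")
  enc_o <- term_encode(tr$object, tr$object_kind, tr$datatype)
  ord <- order(enc_s, enc_p, enc_o, method = "radix")
  vars <- list()
  nm <- character(0)
  if (is_var(subject)) {
    vars <- c(vars, list(enc_s[ord]))
    nm <- c(nm, substring(subject, 2L))
  }
  if (is_var(predicate)) {
    vars <- c(vars, list(enc_p[ord]))
    nm <- c(nm, substring(predicate, 2L))
  }
  if (is_var(object)) {
    vars <- c(vars, list(enc_o[ord]))
    nm <- c(nm, substring(object, 2L))
  }
  if (length(vars) == 0L) {
    return(data.frame(row.names = seq_len(sum(keep))))
  }
  # the same variable in several positions constrains them to bind equally
  while (anyDuplicated(nm)) {
    dup <- nm[duplicated(nm)][1]
    idx <- which(nm == dup)
    same <- vars[[idx[1]]] == vars[[idx[2]]]
    vars <- lapply(vars[-idx[2]], function(v) v[same])
    nm <- nm[-idx[2]]
  }
  names(vars) <- nm
  as.data.frame(vars, stringsAsFactors = FALSE, optional = TRUE)
}

# --- N-Triples serialization ------------------------------------------------

#' Serialize a graph to N-Triples text
#'
#' One triple per line with a trailing `" ."`; lines are emitted sorted so
#' that serializations diff reproducibly. Literals always carry an explicit
#' datatype IRI, guaranteeing a lossless round trip via [parse_ntriples()].
#'
#' @param graph A `triple_graph`.
#' @return A single character scalar (possibly `""` for an empty graph).
#' @export
serialize_ntriples <- function(graph) {
  stopifnot(inherits(graph, "triple_graph"))
  tr <- graph$triples
  if (nrow(tr) == 0L) return("")
  lines <- paste0("<", tr$subject, "> <", tr$predicate, "> ",
                  term_encode(tr$object, tr$object_kind, tr$datatype), " .")
  paste0(paste(sort(lines, method = "radix"), collapse = "\n"), "\n")
}

#' Parse N-Triples text into a graph
#'
#' @param text N-Triples document (character scalar, or vector of lines).
#' @param namespaces Prefix table attached to the resulting graph.
#' @return A `triple_graph`.
#' @export
parse_ntriples <- function(text, namespaces = tl_prefixes()) {
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- text[!grepl("^\\s*(#|$)", text)]
  g <- triple_graph(namespaces)
  if (length(text) == 0L) return(g)
  re <- paste0(
    '^\\s*<([^>[:space:]]+)>\\s+<([^>[:space:]]+)>\\s+',
    '(<[^>[:space:]]+>|"(?:[^"\\\\]|\\\\.)*"(?:\\^\\^<[^>[:space:]]+>)?)',
    '\\s*\\.\\s*$'
  )
  m <- regmatches(text, regexec(re, text))
  bad <- which(vapply(m, length, integer(1)) != 4L)
  if (length(bad) > 0L) {
    stop("malformed N-Triples line ", bad[1], ": ", text[bad[1]],
         call. = FALSE)
  }
  subs <- vapply(m, `[[`, character(1), 2L)
  preds <- vapply(m, `[[`, character(1), 3L)
  objs <- vapply(m, `[[`, character(1), 4L)
  is_iri_obj <- startsWith(objs, "<")
  obj_val <- character(length(objs))
  obj_dt <- rep(NA_character_, length(objs))
  obj_val[is_iri_obj] <- substr(objs[is_iri_obj], 2L,
                                nchar(objs[is_iri_obj]) - 1L)
  if (any(!is_iri_obj)) {
    lit <- objs[!is_iri_obj]
    lm <- regmatches(lit, regexec('^"((?:[^"\\\\]|\\\\.)*)"(\\^\\^<([^>]+)>)?$',
                                  lit))
    obj_val[!is_iri_obj] <- unescape_nt(vapply(lm, `[[`, character(1), 2L))
    dts <- vapply(lm, function(z) if (nzchar(z[4])) z[4] else
      paste0(namespaces[["xsd"]], "string"), character(1))
    obj_dt[!is_iri_obj] <- dts
  }
  rows <- data.frame(subject = subs, predicate = preds, object = obj_val,
                     object_kind = ifelse(is_iri_obj, "iri", "literal"),
                     datatype = obj_dt, stringsAsFactors = FALSE)
  if (!all(is_absolute_iri(subs)) || !all(is_absolute_iri(preds))) {
    stop("malformed IRI in N-Triples input", call. = FALSE)
  }
  add_triple_rows(g, rows)
}

#' Write / read a graph as an N-Triples file (UTF-8)
#' @param graph A `triple_graph`.
#' @param path File path.
#' @return `write_ntriples` returns `path` invisibly; `read_ntriples`
#'   returns a `triple_graph`.
#' @export
write_ntriples <- function(graph, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(serialize_ntriples(graph))), con)
  invisible(path)
}

#' @rdname write_ntriples
#' @param namespaces Prefix table attached to the graph read back.
#' @export
read_ntriples <- function(path, namespaces = tl_prefixes()) {
  parse_ntriples(readLines(path, encoding = "UTF-8", warn = FALSE),
                 namespaces)
}
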