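# Declarative table -> graph mappings (an R2RML-style subset): subject IRI
# templates, constant predicates, column-valued objects with datatypes and
# named value transforms (date normalization, codebook decoding). Also the
# gridded-field bounding-box subset that turns array data into a logical
# table prior to uplift.

#' Normalize a date string to the xsd:date lexical form
#'
#' Source tables carry dates in local conventions (e.g. `dd-MM-yyyy`); all
#' date literals in the graph use the standard `yyyy-MM-dd` form.
#'
#' @param raw Character vector of raw date strings.
#' @param input_pattern Input convention, one of `"dd-MM-yyyy"`,
#'   `"dd/MM/yyyy"`, `"yyyy-MM-dd"`, `"MM/dd/yyyy"`.
#' @return Character vector of `yyyy-MM-dd` lexicals.
#' @export
#' @examples
#' normalize_date("20-10-1985", "dd-MM-yyyy")
normalize_date <- function(raw, input_pattern = "dd-MM-yyyy") {
  fmt <- switch(input_pattern,
    "dd-MM-yyyy" = "%d-%m-%Y",
    "dd/MM/yyyy" = "%d/%m/%Y",
    "yyyy-MM-dd" = "%Y-%m-%d",
    "MM/dd/yyyy" = "%m/%d/%Y",
    stop("unsupported date pattern: ", input_pattern, call. = FALSE)
  )
  d <- as.Date(raw, format = fmt)
  # as.Date silently rolls nothing in R, it returns NA for impossible dates,
  # but accepts e.g. "1-1-2000"; re-format to confirm a full round trip
  bad <- is.na(d)
  if (any(bad)) {
    stop("unparseable or invalid calendar date: ", dQuote(raw[bad][1]),
         " for pattern ", input_pattern, call. = FALSE)
  }
  format(d, "%Y-%m-%d")
}

#' Decode a coded field via a codebook
#'
#' E.g. a patient table encodes gender as `0`/`1`; the graph carries the
#' decoded label (`"Female"`/`"Male"`).
#'
#' @param raw Character vector of codes.
#' @param codebook Named character vector or list mapping code to label.
#' @param unmapped Policy for codes absent from the codebook: `"error"`
#'   (default) or `"passthrough"`.
#' @param column Column name used in error messages.
#' @return Character vector of decoded labels.
#' @export
#' @examples
#' decode_code("0", c("0" = "Female", "1" = "Male"))
decode_code <- function(raw, codebook, unmapped = c("error", "passthrough"),
                        column = "<unknown>") {
  unmapped <- match.arg(unmapped)
  if (length(codebook) == 0L) stop("codebook is empty", call. = FALSE)
  codebook <- unlist(codebook)
  hit <- match(raw, names(codebook))
  if (anyNA(hit) && unmapped == "error") {
    stop("unmapped code ", dQuote(raw[which(is.na(hit))[1]]),
         " in column ", column, call. = FALSE)
  }
  out <- unname(codebook[hit])
  out[is.na(hit)] <- raw[is.na(hit)]
  out
}

#' Percent-encode a string for use inside an IRI (RFC 3986)
#'
#' Unreserved characters and sub-delims (including parentheses) are kept;
#' everything else — notably spaces — is percent-encoded byte-wise in UTF-8.
#'
#' @param x Character vector.
#' @return Percent-encoded character vector.
#' @export
#' @examples
#' percent_encode("Mullingar Automatic Weather Station (AWS)")
percent_encode <- function(x) {
  keep <- c(LETTERS, letters, 0:9, "-", ".", "_", "~",
            "!", "$", "&", "'", "(", ")", "*", "+", ",", ";", "=")
  vapply(x, function(s) {
    bytes <- charToRaw(enc2utf8(s))
    chars <- vapply(as.integer(bytes), function(b) {
      ch <- rawToChar(as.raw(b))
      if (b < 128L && ch %in% keep) ch else sprintf("%%%02X", b)
    }, character(1))
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# --- term templates ---------------------------------------------------------

#' Build a term template
#'
#' A template is a string with `{column}` placeholders plus the kind of term
#' it produces. IRI templates percent-encode each substituted value; literal
#' templates optionally apply a named transform and attach a datatype.
#'
#' @param template Template string, e.g.
#'   `"http://data.avert.ie/patient/{PatientID}"` or `"POINT ({lon} {lat})"`.
#' @param term_kind `"iri"` or `"literal"`.
#' @param datatype Datatype CURIE/IRI for literal templates.
#' @param transform Optional transform spec: `list(kind = "date", pattern =
#'   "dd-MM-yyyy")` or `list(kind = "decode", codebook = c(...), unmapped =
#'   "error")`.
#' @return A `term_template` object.
#' @export
term_template <- function(template, term_kind = c("literal", "iri"),
                          datatype = "xsd:string", transform = NULL) {
  term_kind <- match.arg(term_kind)
  stopifnot(is.character(template), length(template) == 1L)
  structure(list(template = template, term_kind = term_kind,
                 datatype = datatype, transform = transform),
            class = "term_template")
}

template_columns <- function(template) {
  m <- gregexpr("\\{([^{}]+)\\}", template)[[1]]
  if (m[1] == -1L) return(character(0))
  vapply(regmatches(template, gregexpr("\\{([^{}]+)\\}", template))[[1]],
         function(s) substr(s, 2L, nchar(s) - 1L), character(1),
         USE.NAMES = FALSE)
}

apply_transform <- function(value, transform, column) {
  if (is.null(transform)) return(value)
  kind <- transform$kind
  if (identical(kind, "date")) {
    normalize_date(value, transform$pattern %||% "dd-MM-yyyy")
  } else if (identical(kind, "decode")) {
    decode_code(value, transform$codebook,
                unmapped = transform$unmapped %||% "error", column = column)
  } else {
    stop("unknown transform kind: ", kind, call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Instantiate a term template against one table row
#'
#' Returns `NULL` (no term; the triple is skipped) when any placeholder
#' column holds the empty string, the missing-value marker in source tables.
#'
#' @param template A [term_template()].
#' @param row Named list / one-row data.frame of character values.
#' @param namespaces Prefix table for datatype expansion.
#' @return A term object, or `NULL` for a missing value.
#' @export
apply_template <- function(template, row, namespaces = tl_prefixes()) {
  stopifnot(inherits(template, "term_template"))
  row <- as.list(row)
  cols <- template_columns(template$template)
  missing_cols <- setdiff(cols, names(row))
  if (length(missing_cols) > 0L) {
    stop("mapping error: column ", dQuote(missing_cols[1]),
         " not present in source table", call. = FALSE)
  }
  vals <- vapply(cols, function(cn) as.character(row[[cn]]), character(1))
  if (any(!nzchar(vals)) || anyNA(vals)) return(NULL)
  if (!is.null(template$transform)) {
    if (length(cols) != 1L) {
      stop("transforms require a single-column template", call. = FALSE)
    }
    vals <- apply_transform(vals, template$transform, cols)
  }
  out <- template$template
  if (template$term_kind == "iri") vals <- percent_encode(vals)
  for (i in seq_along(cols)) {
    out <- sub(paste0("{", cols[i], "}"), vals[i], out, fixed = TRUE)
  }
  if (template$term_kind == "iri") {
    iri(out, namespaces)
  } else {
    dt <- template$datatype
    if (!is.null(template$transform) &&
        identical(template$transform$kind, "date")) {
      dt <- "xsd:date"
    }
    typed_literal(out, dt, namespaces)
  }
}

# --- triples maps -----------------------------------------------------------

#' Build a triples map (one logical table -> graph rule)
#'
#' @param source Name of the logical table the map consumes.
#' @param subject An IRI [term_template()] minting one subject per row.
#' @param types Character vector of class IRIs/CURIEs asserted via
#'   `rdf:type` for every row subject.
#' @param predicate_objects List of `list(predicate = <IRI/CURIE>, object =
#'   <term_template>)` pairs.
#' @return A `triples_map` object.
#' @export
triples_map <- function(source, subject, types = character(0),
                        predicate_objects = list()) {
  stopifnot(inherits(subject, "term_template"),
            identical(subject$term_kind, "iri"))
  if (length(predicate_objects) == 0L) {
    stop("a triples map needs at least one predicate-object map",
         call. = FALSE)
  }
  structure(list(source = source, subject = subject, types = types,
                 predicate_objects = predicate_objects),
            class = "triples_map")
}

#' Execute triples maps over named logical tables
#'
#' For each row of each map's source table: one subject IRI, one `rdf:type`
#' triple per type assertion, and one triple per predicate-object map whose
#' placeholder cells are non-missing. The total triple count therefore
#' equals the sum over rows of (type assertions + non-missing object maps),
#' minus any duplicates collapsed by set semantics.
#'
#' @param maps List of [triples_map()] objects.
#' @param tables Named list of data.frames (all-character columns; empty
#'   string marks a missing cell).
#' @param graph Graph to extend (default: a fresh one).
#' @return A `triple_graph`.
#' @export
execute_mapping <- function(maps, tables, graph = triple_graph()) {
  if (inherits(maps, "triples_map")) maps <- list(maps)
  ns <- graph$namespaces
  errors <- character(0)
  all_rows <- vector("list", length(maps))
  for (mi in seq_along(maps)) {
    map <- maps[[mi]]
    if (!map$source %in% names(tables)) {
      stop("source table ", dQuote(map$source), " not supplied",
           call. = FALSE)
    }
    tab <- tables[[map$source]]
    n <- nrow(tab)
    if (n == 0L) next
    chunks <- vector("list", n)
    for (ri in seq_len(n)) {
      row <- lapply(tab[ri, , drop = FALSE], as.character)
      res <- tryCatch({
        subj <- apply_template(map$subject, row, ns)
        if (is.null(subj)) {
          stop("subject template produced no term (missing key cell)",
               call. = FALSE)
        }
        rows <- list()
        for (ty in map$types) {
          rows[[length(rows) + 1L]] <- c(subj$value,
                                         expand_curie("rdf:type", ns),
                                         expand_curie(ty, ns), "iri",
                                         NA_character_)
        }
        for (po in map$predicate_objects) {
          obj <- apply_template(po$object, row, ns)
          if (is.null(obj)) next
          if (obj$kind == "iri") {
            rows[[length(rows) + 1L]] <- c(subj$value,
                                           expand_curie(po$predicate, ns),
                                           obj$value, "iri", NA_character_)
          } else {
            rows[[length(rows) + 1L]] <- c(subj$value,
                                           expand_curie(po$predicate, ns),
                                           obj$lexical, "literal",
                                           obj$datatype)
          }
        }
        rows
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors <- c(errors, paste0("table ", map$source, " row ", ri, ": ",
                                   conditionMessage(res)))
      } else {
        chunks[[ri]] <- res
      }
    }
    flat <- unlist(chunks, recursive = FALSE)
    if (length(flat) > 0L) {
      mat <- do.call(rbind, flat)
      all_rows[[mi]] <- data.frame(subject = mat[, 1], predicate = mat[, 2],
                                   object = mat[, 3], object_kind = mat[, 4],
                                   datatype = mat[, 5],
                                   stringsAsFactors = FALSE)
    }
  }
  if (length(errors) > 0L) {
    stop("uplift failed for ", length(errors), " row(s):\n  ",
         paste(utils::head(errors, 5L), collapse = "\n  "), call. = FALSE)
  }
  all_rows <- all_rows[!vapply(all_rows, is.null, logical(1))]
  if (length(all_rows) > 0L) {
    graph <- add_triple_rows(graph, do.call(rbind, all_rows))
  }
  graph
}

# --- gridded fields ---------------------------------------------------------

#' Construct an in-memory gridded field
#'
#' The array model behind NetCDF-style climate/pollution inputs: a 3-D value
#' array on strictly monotone time, latitude and longitude axes.
#'
#' @param time_axis `Date` vector (strictly increasing).
#' @param lat_axis,lon_axis Numeric degree vectors (strictly increasing).
#' @param values Numeric array with dim `c(time, lat, lon)`.
#' @param variable_name Variable name used as the value column on subset.
#' @param units Unit string (metadata only).
#' @return A `gridded_field` object.
#' @export
gridded_field <- function(time_axis, lat_axis, lon_axis, values,
                          variable_name, units = "") {
  time_axis <- as.Date(time_axis)
  stopifnot(all(diff(as.numeric(time_axis)) > 0),
            all(diff(lat_axis) > 0), all(diff(lon_axis) > 0))
  if (!identical(dim(values),
                 c(length(time_axis), length(lat_axis), length(lon_axis)))) {
    stop("values array shape must be (time, lat, lon) matching the axes",
         call. = FALSE)
  }
  structure(list(time_axis = time_axis, lat_axis = lat_axis,
                 lon_axis = lon_axis, values = values,
                 variable_name = variable_name, units = units),
            class = "gridded_field")
}

#' Subset a gridded field to a logical table
#'
#' Keeps every (time, lat, lon) cell whose centre lies inside the closed
#' bounding box and whose date falls in the closed date range, and returns
#' one row per kept cell — the tabular form that is subsequently uplifted.
#' A bounding box disjoint from the grid yields an empty table.
#'
#' @param field A [gridded_field()].
#' @param bbox Numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param dates `c(start, end)` coercible to `Date` (closed range).
#' @return A data.frame with character columns `date`, `lat`, `lon` and the
#'   field's variable name; row count is `n_dates * n_lats * n_lons` kept.
#' @export
subset_grid <- function(field, bbox, dates) {
  stopifnot(inherits(field, "gridded_field"), length(bbox) == 4L)
  if (bbox[1] > bbox[2] || bbox[3] > bbox[4]) {
    stop("invalid bbox: min must not exceed max", call. = FALSE)
  }
  dates <- as.Date(dates)
  if (dates[1] > dates[2]) stop("invalid date range", call. = FALSE)
  ti <- which(field$time_axis >= dates[1] & field$time_axis <= dates[2])
  la <- which(field$lat_axis >= bbox[3] & field$lat_axis <= bbox[4])
  lo <- which(field$lon_axis >= bbox[1] & field$lon_axis <= bbox[2])
  n <- length(ti) * length(la) * length(lo)
  if (n == 0L) {
    return(data.frame(date = character(0), lat = character(0),
                      lon = character(0),
                      stats::setNames(list(character(0)),
                                      field$variable_name),
                      stringsAsFactors = FALSE, check.names = FALSE))
  }
  # expand in (time, lat, lon) lexicographic order
  idx <- expand.grid(lon = lo, lat = la, time = ti,
                     KEEP.OUT.ATTRS = FALSE)[, c("time", "lat", "lon")]
  idx <- idx[order(idx$time, idx$lat, idx$lon), , drop = FALSE]
  vals <- field$values[cbind(idx$time, idx$lat, idx$lon)]
  out <- data.frame(
    date = format(field$time_axis[idx$time], "%Y-%m-%d"),
    lat = as.character(field$lat_axis[idx$lat]),
    lon = as.character(field$lon_axis[idx$lon]),
    stats::setNames(list(ifelse(is.na(vals), "", as.character(vals))),
                    field$variable_name),
    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read a gridded field as a long-format CSV
#'
#' A plain-text stand-in for array-file storage: columns `date`, `lat`,
#' `lon`, `value` plus a header comment carrying the variable name and
#' units. Lossless for the grid values at full `as.character` precision.
#'
#' @param field A [gridded_field()].
#' @param path File path.
#' @return `read_grid_csv` returns a `gridded_field`.
#' @export
write_grid_csv <- function(field, path) {
  tab <- subset_grid(field,
                     c(min(field$lon_axis), max(field$lon_axis),
                       min(field$lat_axis), max(field$lat_axis)),
                     range(field$time_axis))
  names(tab)[4] <- "value"
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- paste0("# variable=", field$variable_name, " units=", field$units,
                "\n")
  writeBin(charToRaw(enc2utf8(hdr)), con)
  writeBin(charToRaw(paste0(paste(names(tab), collapse = ","), "\n")), con)
  body <- do.call(paste, c(as.list(tab), sep = ","))
  if (length(body) > 0L) {
    writeBin(charToRaw(enc2utf8(paste0(paste(body, collapse = "\n"), "\n"))),
             con)
  }
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- regmatches(first,
                     regexec("^# variable=(\\S+) units=(.*)$", first))[[1]]
  tab <- utils::read.csv(path, comment.char = "#", colClasses = "character")
  dates <- sort(unique(as.Date(tab$date)))
  lats <- sort(unique(as.numeric(tab$lat)))
  lons <- sort(unique(as.numeric(tab$lon)))
  arr <- array(NA_real_, dim = c(length(dates), length(lats), length(lons)))
  ti <- match(as.Date(tab$date), dates)
  la <- match(as.numeric(tab$lat), lats)
  lo <- match(as.numeric(tab$lon), lons)
  arr[cbind(ti, la, lo)] <- ifelse(nzchar(tab$value),
                                   as.numeric(tab$value), NA_real_)
  gridded_field(dates, lats, lons, arr,
                variable_name = meta[2], units = meta[3])
}
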