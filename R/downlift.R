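# Downlift: project the enriched graph back to a per-patient analytic table.
# One row per patient (case-level), combining copied clinical attributes with
# exposure-window aggregates of the observations recorded at the patient's
# nearest weather station.

#' Aggregate a numeric series with a missing-value policy
#'
#' @param values Numeric vector, `NA` marking missing observations.
#' @param kind `"mean"`, `"sum"`, `"min"`, `"max"` or `"count"`.
#' @param policy `"skip"` aggregates over the non-missing values;
#'   `"strict"` returns `NA` as soon as any value is missing. An empty
#'   input yields `NA` (`count` yields 0; it always counts non-missing).
#' @return Numeric scalar or `NA`.
#' @export
#' @examples
#' aggregate_values(c(2, NA, 6), "mean", "skip")    # 4
#' aggregate_values(c(2, NA, 6), "mean", "strict")  # NA
aggregate_values <- function(values, kind = c("mean", "sum", "min", "max",
                                              "count"),
                             policy = c("skip", "strict")) {
  kind <- match.arg(kind)
  policy <- match.arg(policy)
  if (kind == "count") return(sum(!is.na(values)))
  if (length(values) == 0L) return(NA_real_)
  if (policy == "strict" && anyNA(values)) return(NA_real_)
  v <- values[!is.na(values)]
  if (length(v) == 0L) return(NA_real_)
  switch(kind, mean = mean(v), sum = sum(v), min = min(v), max = max(v))
}

#' Build a projection specification for downlift
#'
#' @param columns List of column specs. Each is either
#'   `list(name =, attribute = <predicate>)` (copy the patient's literal /
#'   IRI value bit-exactly) or
#'   `list(name =, aggregate = list(predicate =, kind =, policy = ))`
#'   (window-aggregate the named numeric observation predicate at the
#'   patient's nearest station).
#' @param window `list(n_days =, include_diagnosis =)` defining the
#'   exposure window around each patient's `avert:diagnosisDate`.
#' @return A `projection_spec` object.
#' @export
projection_spec <- function(columns,
                            window = list(n_days = 7,
                                          include_diagnosis = FALSE)) {
  nms <- vapply(columns, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("projection column names must be unique", call. = FALSE)
  }
  if (is.null(window$n_days) || window$n_days < 1) {
    stop("projection window must be at least 1 day", call. = FALSE)
  }
  window$include_diagnosis <- isTRUE(window$include_diagnosis)
  structure(list(columns = columns, window = window),
            class = "projection_spec")
}

# all (subject, value-lexical) pairs for one predicate, as a lookup frame
predicate_frame <- function(graph, predicate) {
  m <- match_pattern(graph, "?s", predicate, "?o")
  data.frame(subject = term_value(m$s), value = term_value(m$o),
             stringsAsFactors = FALSE)
}

#' Downlift the enriched graph to a per-patient table
#'
#' Produces exactly one row per `avert:Patient`, ordered by patient IRI.
#' Attribute columns copy the patient's stored lexical forms bit-exactly;
#' aggregate columns fetch the observations of the patient's
#' `avert:nearestStation` whose `avert:onDate` falls inside the patient's
#' [exposure_window()] and reduce them with [aggregate_values()]. Computed
#' aggregates are formatted with the shortest decimal representation that
#' round-trips the double. A downlift provenance activity is recorded in a
#' copy of the graph attached as `attr(result, "provenance_graph")`.
#'
#' @param graph Enriched `triple_graph` (nearest-station links present).
#' @param spec A [projection_spec()].
#' @param agent,clock Provenance identity and timestamp source.
#' @return A data.frame with `patient` plus one column per spec column;
#'   missing values are `NA`.
#' @export
build_enriched_table <- function(graph, spec, agent = default_agent(),
                                 clock = Sys.time) {
  stopifnot(inherits(spec, "projection_spec"))
  started <- clock()
  ns <- graph$namespaces
  known_preds <- unique(graph$triples$predicate)
  for (col in spec$columns) {
    pred <- if (!is.null(col$attribute)) col$attribute
            else col$aggregate$predicate
    if (!expand_curie(pred, ns) %in% known_preds) {
      stop("projection references unknown predicate: ", pred, call. = FALSE)
    }
  }
  pats <- match_pattern(graph, "?p", "rdf:type", "avert:Patient")
  patients <- sort(term_value(pats$p), method = "radix")

  nearest <- predicate_frame(graph, "avert:nearestStation")
  diag_date <- predicate_frame(graph, "avert:diagnosisDate")
  obs_station <- predicate_frame(graph, "avert:atStation")
  obs_date <- predicate_frame(graph, "avert:onDate")

  out <- data.frame(patient = patients, stringsAsFactors = FALSE)
  for (col in spec$columns) {
    if (!is.null(col$attribute)) {
      pf <- predicate_frame(graph, col$attribute)
      out[[col$name]] <- pf$value[match(patients, pf$subject)]
    } else {
      agg <- col$aggregate
      vf <- predicate_frame(graph, agg$predicate)
      vals <- rep(NA_character_, length(patients))
      for (i in seq_along(patients)) {
        st <- nearest$value[match(patients[i], nearest$subject)]
        dd <- diag_date$value[match(patients[i], diag_date$subject)]
        if (is.na(st) || is.na(dd)) next
        win <- exposure_window(dd, spec$window$n_days,
                               spec$window$include_diagnosis)
        obs <- obs_station$subject[obs_station$value == st]
        dts <- as.Date(obs_date$value[match(obs, obs_date$subject)])
        obs <- obs[!is.na(dts) & dts >= win[1] & dts <= win[2]]
        raw <- vf$value[match(obs, vf$subject)]
        x <- suppressWarnings(as.numeric(raw))
        if (any(!is.na(raw) & is.na(x))) {
          stop("non-numeric value under predicate ", agg$predicate,
               call. = FALSE)
        }
        a <- aggregate_values(x, agg$kind, agg$policy %||% "skip")
        if (!is.na(a)) vals[i] <- shortest_decimal(a)
      }
      out[[col$name]] <- vals
    }
  }
  rownames(out) <- NULL
  act <- prov_activity(
    id = next_activity_iri(graph, "downlift"),
    started = started, ended = clock(), agent = agent,
    used = "http://data.avert.ie/dataset/graph",
    generated = "http://data.avert.ie/entity/enriched_table")
  attr(out, "provenance_graph") <- record_activity(graph, act)
  out
}

#' Write / read the enriched table as CSV
#'
#' RFC 4180 quoting (fields containing commas, quotes or newlines are
#' quoted, embedded quotes doubled); `NA` cells are written as the
#' `na_marker` (default: empty field) and mapped back to `NA` on read, so
#' a write/read cycle reproduces the rows exactly.
#'
#' @param rows data.frame of character columns (as from
#'   [build_enriched_table()]).
#' @param path File path.
#' @param na_marker String written for `NA` cells.
#' @return `read_enriched_csv` returns the data.frame (all-character).
#' @export
write_enriched_csv <- function(rows, path, na_marker = "") {
  esc <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- na_marker
    needs <- grepl('[",\n\r]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(esc(names(rows)), collapse = ","),
             if (nrow(rows) > 0L) {
               do.call(paste, c(lapply(rows, esc), list(sep = ",")))
             })
  writeBin(charToRaw(enc2utf8(paste0(paste(lines, collapse = "\n"), "\n"))),
           con)
  invisible(path)
}

#' @rdname write_enriched_csv
#' @export
read_enriched_csv <- function(path, na_marker = "") {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  for (j in seq_along(df)) df[[j]][df[[j]] == na_marker] <- NA_character_
  df
}
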