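# Conjunctive triple-pattern queries over the graph: per-pattern matching,
# sort-merge natural join on shared variables, then temporal / spatial /
# exclusion filters and projection. Also the temporal-granularity helpers:
# ISO week numbering and pre-diagnosis exposure windows.

#' Build a query specification
#'
#' @param patterns List of triple patterns, each `list(s =, p =, o =)` with
#'   concrete terms (IRI/CURIE strings or term objects) or variables
#'   (`"?name"`).
#' @param filters List of filters, each a list with a `kind` field:
#'   \describe{
#'     \item{date_range}{`var`, `start`, `end` — keep bindings whose
#'       xsd:date value lies in the closed range.}
#'     \item{within_region}{`var`, `region` — keep point literals falling
#'       inside the polygon of the region IRI (looked up in the graph).}
#'     \item{within_radius}{`var`, `centre_lon`, `centre_lat`, `radius_km`
#'       — keep point literals within the closed great-circle radius.}
#'     \item{exclude_has_triple}{`var`, `predicate`, `object` — drop rows
#'       whose bound entity has the given triple (e.g. a comorbidity).}
#'     \item{week_equals}{`var`, `week` — keep xsd:date values in the given
#'       ISO week (`"2016-W01"`).}
#'   }
#' @param projection Character vector of variable names to keep.
#' @return A `query_spec` object.
#' @export
query_spec <- function(patterns, filters = list(), projection = NULL) {
  vars <- unique(unlist(lapply(patterns, function(p) {
    v <- c(p$s, p$p, p$o)
    v <- v[vapply(v, function(x) is.character(x) && startsWith(x, "?"),
                  logical(1))]
    substring(unlist(v), 2L)
  })))
  if (is.null(projection)) projection <- vars
  unknown <- setdiff(projection, vars)
  if (length(unknown) > 0L) {
    stop("projected variable not bound by any pattern: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (f in filters) {
    if (!is.null(f$var) && !f$var %in% vars) {
      stop("filter variable not bound by any pattern: ", f$var,
           call. = FALSE)
    }
  }
  structure(list(patterns = patterns, filters = filters,
                 projection = projection),
            class = "query_spec")
}

cross_join <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    out <- cbind(a[0L, , drop = FALSE], b[0L, , drop = FALSE])
    rownames(out) <- NULL
    return(out)
  }
  out <- cbind(a[rep(seq_len(nrow(a)), each = nrow(b)), , drop = FALSE],
               b[rep(seq_len(nrow(b)), times = nrow(a)), , drop = FALSE])
  rownames(out) <- NULL
  out
}

apply_query_filter <- function(bind, f, graph) {
  if (nrow(bind) == 0L) return(bind)
  v <- bind[[f$var]]
  keep <- switch(f$kind,
    date_range = {
      d <- as.Date(term_value(v))
      !is.na(d) & d >= as.Date(f$start) & d <= as.Date(f$end)
    },
    week_equals = {
      d <- term_value(v)
      vapply(d, function(x) format_iso_week(iso_week_of(x)) == f$week,
             logical(1), USE.NAMES = FALSE)
    },
    within_radius = {
      vapply(term_value(v), function(w) {
        p <- parse_wkt_point(w)
        haversine_km_lonlat(p$lon, p$lat, f$centre_lon, f$centre_lat) <=
          f$radius_km
      }, logical(1), USE.NAMES = FALSE)
    },
    within_region = {
      regs <- graph_regions(graph)
      ids <- vapply(regs, `[[`, character(1), "id")
      target <- expand_curie(f$region, graph$namespaces)
      hit <- match(target, ids)
      if (is.na(hit)) stop("region not in graph: ", f$region, call. = FALSE)
      poly <- regs[[hit]]$polygon
      vapply(term_value(v), function(w) {
        point_in_polygon(parse_wkt_point(w), poly)
      }, logical(1), USE.NAMES = FALSE)
    },
    exclude_has_triple = {
      obj <- f$object
      vapply(term_value(v), function(ent) {
        !graph_contains(graph, ent, f$predicate, obj)
      }, logical(1), USE.NAMES = FALSE)
    },
    stop("unknown filter kind: ", f$kind, call. = FALSE)
  )
  bind[keep, , drop = FALSE]
}

#' Evaluate a conjunctive query
#'
#' Matches each pattern, natural-joins the match sets on shared variables,
#' applies the filters (filters commute, so their order is irrelevant),
#' projects, and sorts rows lexicographically for a deterministic result.
#' Binding values are N-Triples-encoded terms ([term_value()] decodes).
#'
#' @param graph A `triple_graph`.
#' @param spec A [query_spec()].
#' @return A data.frame with one column per projected variable.
#' @export
evaluate_query <- function(graph, spec) {
  stopifnot(inherits(spec, "query_spec"))
  bind <- NULL
  for (p in spec$patterns) {
    m <- match_pattern(graph, p$s %||% "?s", p$p %||% "?p", p$o %||% "?o")
    if (is.null(bind)) {
      bind <- m
    } else if (ncol(m) == 0L) {
      # fully concrete pattern: acts as an existence test
      if (nrow(m) == 0L) bind <- bind[0L, , drop = FALSE]
    } else if (ncol(bind) == 0L) {
      if (nrow(bind) > 0L) bind <- m else bind <- m[0L, , drop = FALSE]
    } else {
      shared <- intersect(names(bind), names(m))
      bind <- if (length(shared) == 0L) cross_join(bind, m)
              else merge(bind, m, by = shared)
    }
    if (nrow(bind) == 0L) break
  }
  if (is.null(bind)) bind <- data.frame()
  for (f in spec$filters) bind <- apply_query_filter(bind, f, graph)
  # an early-emptied join may not have reached patterns binding the
  # remaining projected variables; supply them as empty columns
  for (v in setdiff(spec$projection, names(bind))) {
    bind[[v]] <- character(nrow(bind))
  }
  bind <- bind[, spec$projection, drop = FALSE]
  if (nrow(bind) > 0L) {
    ord <- do.call(order, c(unname(as.list(bind)), list(method = "radix")))
    bind <- bind[ord, , drop = FALSE]
  }
  rownames(bind) <- NULL
  bind
}

# --- temporal helpers -------------------------------------------------------

#' ISO-8601 week of a date
#'
#' Weekly surveillance counts are keyed by ISO week; this returns the
#' ISO-8601 week-numbering year and week (1-53) of a date, in which weeks
#' start on Monday and week 1 contains the year's first Thursday.
#'
#' @param date `Date` or `yyyy-MM-dd` string.
#' @return An `iso_week` object (fields `year`, `week`).
#' @export
#' @examples
#' format_iso_week(iso_week_of("2016-01-04"))  # "2016-W01"
#' format_iso_week(iso_week_of("2016-01-03"))  # "2015-W53"
iso_week_of <- function(date) {
  d <- tryCatch(as.Date(date), error = function(e) NA)
  if (is.na(d)) stop("invalid date: ", date, call. = FALSE)
  structure(list(year = as.integer(format(d, "%G")),
                 week = as.integer(format(d, "%V"))),
            class = "iso_week")
}

#' @rdname iso_week_of
#' @param w An `iso_week`.
#' @export
format_iso_week <- function(w) {
  stopifnot(inherits(w, "iso_week"))
  sprintf("%04d-W%02d", w$year, w$week)
}

#' Pre-diagnosis exposure window
#'
#' The closed date interval over which a patient's environmental exposures
#' are aggregated: by default the `n_days` days strictly before diagnosis,
#' `[diagnosis - n_days, diagnosis - 1]`; with
#' `include_diagnosis = TRUE` the window shifts to end on the diagnosis day
#' itself, `[diagnosis - n_days + 1, diagnosis]`. Either way the window is
#' exactly `n_days` long.
#'
#' @param diagnosis_date `Date` or `yyyy-MM-dd` string.
#' @param n_days Window length in days (>= 1).
#' @param include_diagnosis Include the diagnosis day itself?
#' @return `Date` vector `c(start, end)`.
#' @export
#' @examples
#' exposure_window("2015-03-10", 7)
exposure_window <- function(diagnosis_date, n_days,
                            include_diagnosis = FALSE) {
  if (!is.numeric(n_days) || n_days < 1) {
    stop("n_days must be a positive integer", call. = FALSE)
  }
  d <- as.Date(diagnosis_date)
  if (is.na(d)) stop("invalid diagnosis date", call. = FALSE)
  if (include_diagnosis) c(d - n_days + 1L, d) else c(d - n_days, d - 1L)
}

#' Link weekly regional counts onto patients
#'
#' Weekly surveillance records (`rdf:type avert:WeeklyCount` with
#' `avert:region`, `avert:isoWeek`, `avert:count`) are keyed by
#' (region, ISO week). Every patient carrying `avert:withinRegion` and
#' `avert:diagnosisDate` whose (region, diagnosis week) key exists gains
#' one `avert:diagnosisWeekCount` triple; patients without a matching
#' record gain none. Duplicate (region, week) records are a data error.
#' Idempotent; records a provenance activity for the batch.
#'
#' @param graph A `triple_graph`.
#' @param agent Provenance agent identity.
#' @param clock Timestamp source (see [materialize_spatial_links()]).
#' @return The enriched `triple_graph`.
#' @export
link_weekly_counts <- function(graph, agent = default_agent(),
                               clock = Sys.time) {
  started <- clock()
  recs <- match_pattern(graph, "?c", "rdf:type", "avert:WeeklyCount")
  key <- character(0)
  counts <- character(0)
  for (c_iri in term_value(recs$c)) {
    r <- match_pattern(graph, c_iri, "avert:region", "?r")
    w <- match_pattern(graph, c_iri, "avert:isoWeek", "?w")
    n <- match_pattern(graph, c_iri, "avert:count", "?n")
    if (nrow(r) == 0L || nrow(w) == 0L || nrow(n) == 0L) next
    k <- paste(term_value(r$r[1]), term_value(w$w[1]), sep = "\r")
    if (k %in% key) {
      stop("duplicate weekly count record for (region, week): ",
           sub("\r", ", ", k, fixed = TRUE), call. = FALSE)
    }
    key <- c(key, k)
    counts <- c(counts, term_value(n$n[1]))
  }
  pats <- match_pattern(graph, "?p", "rdf:type", "avert:Patient")
  for (p_iri in term_value(pats$p)) {
    reg <- match_pattern(graph, p_iri, "avert:withinRegion", "?r")
    dg <- match_pattern(graph, p_iri, "avert:diagnosisDate", "?d")
    if (nrow(reg) == 0L || nrow(dg) == 0L) next
    wk <- format_iso_week(iso_week_of(term_value(dg$d[1])))
    k <- paste(term_value(reg$r[1]), wk, sep = "\r")
    hit <- match(k, key)
    if (is.na(hit)) next
    graph <- add_triple(graph, p_iri, "avert:diagnosisWeekCount",
                        typed_literal(counts[hit], "xsd:integer"))
  }
  act <- prov_activity(
    id = next_activity_iri(graph, "weekly-counts"),
    started = started, ended = clock(), agent = agent,
    used = c("http://data.avert.ie/dataset/weekly_counts",
             "http://data.avert.ie/dataset/patients"),
    generated = enrichment_batch_iris("diagnosisWeekCount"))
  record_activity(graph, act)
}
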