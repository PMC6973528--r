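# PROV-style provenance: every enrichment / query / downlift execution is
# recorded as an activity with start/end timestamps, an agent, the dataset
# entities it used and the entities it generated. Generated entities are
# reified at batch granularity (one IRI per enrichment predicate batch), not
# one entity per triple, keeping the provenance subgraph small.

# predicates whose triples must be provenance-covered
ENRICHMENT_PREDICATES <- c("nearestStation", "nearestStationDistanceKm",
                           "withinRegion", "diagnosisWeekCount")

enrichment_batch_iris <- function(locals) {
  paste0("http://data.avert.ie/entity/enrichment/", locals)
}

# deterministic fresh activity IRI: stage name + 1-based counter scanning
# activities already in the graph
next_activity_iri <- function(graph, stage) {
  existing <- match_pattern(graph, "?a", "rdf:type", "prov:Activity")
  n <- 0L
  if (nrow(existing) > 0L) {
    ids <- term_value(existing$a)
    pre <- paste0("http://data.avert.ie/activity/", stage, "/")
    nums <- suppressWarnings(as.integer(sub(pre, "", ids[startsWith(ids, pre)],
                                            fixed = TRUE)))
    if (length(nums) > 0L && !all(is.na(nums))) n <- max(nums, na.rm = TRUE)
  }
  paste0("http://data.avert.ie/activity/", stage, "/", n + 1L)
}

format_xsd_datetime <- function(t) {
  format(as.POSIXct(t, tz = "UTC"), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Construct a provenance activity record
#'
#' @param id Activity IRI (unique within the graph).
#' @param started,ended POSIXct (or parseable) timestamps, `started <=
#'   ended`.
#' @param agent Agent identity: a full IRI, or a plain name minted under
#'   `http://data.avert.ie/agent/`.
#' @param used Character vector of input entity IRIs.
#' @param generated Character vector of output entity IRIs.
#' @return A `prov_activity` object.
#' @export
prov_activity <- function(id, started, ended, agent,
                          used = character(0), generated = character(0)) {
  started <- as.POSIXct(started, tz = "UTC")
  ended <- as.POSIXct(ended, tz = "UTC")
  if (ended < started) {
    stop("activity ended before it started", call. = FALSE)
  }
  if (!grepl("://", agent)) {
    agent <- paste0("http://data.avert.ie/agent/", percent_encode(agent))
  }
  structure(list(id = iri(id)$value, started = started, ended = ended,
                 agent = iri(agent)$value,
                 used = vapply(used, function(u) iri(u)$value, character(1),
                               USE.NAMES = FALSE),
                 generated = vapply(generated, function(u) iri(u)$value,
                                    character(1), USE.NAMES = FALSE)),
            class = "prov_activity")
}

#' Record a provenance activity in the graph
#'
#' Adds four core triples (`rdf:type prov:Activity`, `prov:startedAtTime`,
#' `prov:endedAtTime`, `prov:wasAssociatedWith`), one `prov:used` triple
#' per input entity and one `prov:wasGeneratedBy` triple per generated
#' entity: `4 + |used| + |generated|` new triples for a fresh activity id.
#'
#' @param graph A `triple_graph`.
#' @param activity A [prov_activity()].
#' @return The graph with the activity recorded.
#' @export
record_activity <- function(graph, activity) {
  stopifnot(inherits(activity, "prov_activity"))
  if (nrow(match_pattern(graph, activity$id, "rdf:type",
                         "prov:Activity")) > 0L) {
    stop("duplicate activity id: ", activity$id, call. = FALSE)
  }
  g <- add_triple(graph, activity$id, "rdf:type", "prov:Activity")
  g <- add_triple(g, activity$id, "prov:startedAtTime",
                  typed_literal(format_xsd_datetime(activity$started),
                                "xsd:dateTime"))
  g <- add_triple(g, activity$id, "prov:endedAtTime",
                  typed_literal(format_xsd_datetime(activity$ended),
                                "xsd:dateTime"))
  g <- add_triple(g, activity$id, "prov:wasAssociatedWith", activity$agent)
  for (u in activity$used) {
    g <- add_triple(g, activity$id, "prov:used", u)
  }
  for (e in activity$generated) {
    g <- add_triple(g, e, "prov:wasGeneratedBy", activity$id)
  }
  g
}

#' Check that every enrichment triple has a generating activity
#'
#' Enrichment batches are reified as entities named after the enrichment
#' predicate (`http://data.avert.ie/entity/enrichment/<local>`); a triple
#' using an enrichment predicate is covered when that batch entity carries
#' `prov:wasGeneratedBy` pointing at a recorded `prov:Activity`. The report
#' lists every uncovered enrichment triple; an empty report means the graph
#' is fully provenanced.
#'
#' @param graph A `triple_graph`.
#' @return A data.frame with columns `subject`, `predicate`, `object`
#'   (encoded terms) of uncovered enrichment triples; zero rows when clean.
#' @export
validate_provenance <- function(graph) {
  ns <- graph$namespaces
  out <- list()
  for (local in ENRICHMENT_PREDICATES) {
    pred <- paste0(ns[["avert"]], local)
    hits <- match_pattern(graph, "?s", pred, "?o")
    if (nrow(hits) == 0L) next
    batch <- enrichment_batch_iris(local)
    gen <- match_pattern(graph, batch, "prov:wasGeneratedBy", "?a")
    covered <- FALSE
    if (nrow(gen) > 0L) {
      acts <- term_value(gen$a)
      covered <- any(vapply(acts, function(a) {
        nrow(match_pattern(graph, a, "rdf:type", "prov:Activity")) > 0L
      }, logical(1)))
    }
    if (!covered) {
      out[[length(out) + 1L]] <- data.frame(
        subject = hits$s, predicate = paste0("<", pred, ">"),
        object = hits$o, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(subject = character(0), predicate = character(0),
                      object = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$subject, res$predicate, res$object, method = "radix"), ,
      drop = FALSE]
}
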