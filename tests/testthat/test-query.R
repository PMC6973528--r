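# Conjunctive queries, temporal helpers and weekly-count linkage.

test_that("single- and multi-pattern joins match the nested-loop oracle", {
  g <- triple_graph()
  g <- add_triple(g, "avert:p1", "rdf:type", "avert:Patient")
  g <- add_triple(g, "avert:p1", "rdfs:label", typed_literal("one"))
  g <- add_triple(g, "avert:p2", "rdf:type", "avert:Patient")
  patterns <- list(list(s = "?s", p = "rdf:type", o = "avert:Patient"),
                   list(s = "?s", p = "rdfs:label", o = "?l"))
  got <- evaluate_query(g, query_spec(patterns, projection = c("s", "l")))
  # resolve CURIEs for the oracle, which works on encoded terms
  ns <- tl_prefixes()
  opat <- list(list(s = "?s", p = paste0("<", ns[["rdf"]], "type>"),
                    o = paste0("<", ns[["avert"]], "Patient>")),
               list(s = "?s", p = paste0("<", ns[["rdfs"]], "label>"),
                    o = "?l"))
  want <- oracle_evaluate(g, opat, c("s", "l"))
  expect_equal(got, want)
  expect_equal(nrow(got), 1L)
})

test_that("random conjunctive queries equal the nested-loop oracle", {
  set.seed(61)
  for (trial in seq_len(200)) {
    g <- random_graph(sample(5:40, 1))
    tr <- g$triples
    n_pat <- sample(1:3, 1)
    patterns <- list()
    opatterns <- list()
    vars <- c("a", "b", "c", "d")
    for (k in seq_len(n_pat)) {
      row <- tr[sample.int(nrow(tr), 1), ]
      pick <- function(conc, enc) {
        if (stats::runif(1) < 0.45) paste0("?", sample(vars, 1))
        else structure(conc, enc = enc)
      }
      s <- pick(row$subject, paste0("<", row$subject, ">"))
      p <- pick(row$predicate, paste0("<", row$predicate, ">"))
      o_enc <- if (row$object_kind == "iri") paste0("<", row$object, ">")
               else term_encode_one(row$object, row$datatype)
      o <- pick(row$object, o_enc)
      as_impl <- function(x, kind) {
        if (startsWith(unclass(x)[1], "?")) return(unclass(x)[1])
        if (kind == "o" && row$object_kind == "literal") {
          typed_literal(unclass(x)[1], row$datatype)
        } else iri(unclass(x)[1])
      }
      patterns[[k]] <- list(s = as_impl(s, "s"), p = as_impl(p, "p"),
                            o = as_impl(o, "o"))
      as_oracle <- function(x) {
        v <- unclass(x)[1]
        if (startsWith(v, "?")) v else attr(x, "enc")
      }
      opatterns[[k]] <- list(s = as_oracle(s), p = as_oracle(p),
                             o = as_oracle(o))
    }
    proj <- unique(unlist(lapply(opatterns, function(pp) {
      v <- unlist(pp)
      substring(v[startsWith(v, "?")], 2L)
    })))
    if (length(proj) == 0L) next
    got <- evaluate_query(g, query_spec(patterns, projection = proj))
    want <- oracle_evaluate(g, opatterns, proj)
    got <- got[, sort(names(got)), drop = FALSE]
    want <- want[, sort(names(want)), drop = FALSE]
    expect_equal(got, want)
  }
})

weekly_fixture_graph <- function(seed = 6) {
  bundle <- generate_fixtures(synthetic_config(seed = seed, n_patients = 6,
                                               n_stations = 3,
                                               n_regions = 4))
  g <- execute_mapping(default_mapping(), bundle$tables)
  g <- materialize_spatial_links(g, agent = "tester",
                                 clock = logical_clock())
  list(g = g, bundle = bundle)
}

test_that("contradictory date ranges yield an empty result", {
  x <- weekly_fixture_graph()
  spec <- query_spec(
    patterns = list(list(s = "?p", p = "avert:diagnosisDate", o = "?d")),
    filters = list(list(kind = "date_range", var = "d",
                        start = "2015-03-01", end = "2015-01-01")),
    projection = "p")
  expect_equal(nrow(evaluate_query(x$g, spec)), 0L)
})

test_that("unknown projected variables are a spec error", {
  expect_error(query_spec(list(list(s = "?s", p = "rdf:type",
                                    o = "avert:Patient")),
                          projection = c("s", "ghost")),
               "ghost")
})

test_that("the federated exemplar matches a hand-computed count", {
  # patients joined to nearest-station observations in a pre-diagnosis
  # window, excluding patients with a comorbidity
  x <- weekly_fixture_graph()
  g <- x$g
  tabs <- x$bundle$tables
  spec <- query_spec(
    patterns = list(
      list(s = "?p", p = "rdf:type", o = "avert:Patient"),
      list(s = "?p", p = "avert:diagnosisDate", o = "?dd"),
      list(s = "?p", p = "avert:nearestStation", o = "?st"),
      list(s = "?obs", p = "avert:atStation", o = "?st"),
      list(s = "?obs", p = "avert:onDate", o = "?od")),
    filters = list(
      list(kind = "exclude_has_triple", var = "p",
           predicate = "avert:comorbidity",
           object = typed_literal("present"))),
    projection = c("p", "obs", "od"))
  got <- evaluate_query(g, spec)

  # counting oracle straight from the fixture tables
  keep <- tabs$patients$Comorbidity == "0"
  n_days <- length(unique(tabs$observations$Date))
  expect_equal(nrow(got), sum(keep) * n_days)

  # adding a window via date_range reduces each patient to window-days
  ans <- x$bundle$answers$nearest_station
  p1 <- tabs$patients[1, ]
  win <- exposure_window(normalize_date(p1$DiagnosisDate), 7)
  spec2 <- query_spec(
    patterns = spec$patterns,
    filters = list(list(kind = "date_range", var = "od",
                        start = win[1], end = win[2])),
    projection = c("p", "od"))
  got2 <- evaluate_query(g, spec2)
  pat1 <- paste0("<http://data.avert.ie/patient/", p1$PatientID, ">")
  expect_equal(sum(got2$p == pat1), 7L)
})

test_that("filters commute", {
  x <- weekly_fixture_graph()
  patterns <- list(
    list(s = "?p", p = "rdf:type", o = "avert:Patient"),
    list(s = "?p", p = "avert:diagnosisDate", o = "?d"))
  filters <- list(
    list(kind = "date_range", var = "d", start = "2015-01-15",
         end = "2015-03-15"),
    list(kind = "exclude_has_triple", var = "p",
         predicate = "avert:comorbidity",
         object = typed_literal("present")),
    list(kind = "week_equals", var = "d",
         week = format_iso_week(iso_week_of("2015-02-04"))))
  base <- evaluate_query(x$g, query_spec(patterns, filters,
                                         projection = c("p", "d")))
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(evaluate_query(x$g, query_spec(patterns, filters[perm],
                                                projection = c("p", "d"))),
                 base)
  }
})

test_that("spatial filters accept point literals", {
  g <- triple_graph()
  g <- add_triple(g, "avert:g1", "geo:asWKT",
                  typed_literal("POINT (-7 53)", "geo:wktLiteral"))
  g <- add_triple(g, "avert:g2", "geo:asWKT",
                  typed_literal("POINT (-6 52)", "geo:wktLiteral"))
  spec <- query_spec(
    patterns = list(list(s = "?s", p = "geo:asWKT", o = "?w")),
    filters = list(list(kind = "within_radius", var = "w",
                        centre_lon = -7, centre_lat = 53,
                        radius_km = 50)),
    projection = "s")
  got <- evaluate_query(g, spec)
  expect_equal(term_value(got$s), expand_curie("avert:g1"))
})

test_that("ISO week numbering matches the ISO-8601 calendar", {
  expect_equal(format_iso_week(iso_week_of("2016-01-04")), "2016-W01")
  expect_equal(format_iso_week(iso_week_of("2016-01-03")), "2015-W53")
  expect_equal(format_iso_week(iso_week_of("2015-12-31")), "2015-W53")
  expect_error(iso_week_of("not-a-date"), "invalid")
  # week stability: a Monday and the following Sunday share a week
  set.seed(41)
  for (i in 1:25) {
    d <- as.Date("2014-01-06") + 7L * sample.int(200, 1)  # Mondays
    expect_equal(format_iso_week(iso_week_of(d)),
                 format_iso_week(iso_week_of(d + 6L)))
    expect_false(format_iso_week(iso_week_of(d)) ==
                   format_iso_week(iso_week_of(d + 7L)))
  }
})

test_that("exposure windows are closed, prior and exactly n_days long", {
  expect_equal(exposure_window("2015-03-10", 7),
               as.Date(c("2015-03-03", "2015-03-09")))
  expect_equal(exposure_window("2015-03-01", 1),
               as.Date(c("2015-02-28", "2015-02-28")))
  expect_equal(exposure_window("2016-03-01", 1),
               as.Date(c("2016-02-29", "2016-02-29")))
  expect_equal(exposure_window("2015-03-10", 7, include_diagnosis = TRUE),
               as.Date(c("2015-03-04", "2015-03-10")))
  expect_error(exposure_window("2015-03-10", 0), "positive")
  set.seed(51)
  for (i in 1:50) {
    d <- as.Date("2015-01-01") + sample.int(400, 1)
    n <- sample.int(60, 1)
    inc <- stats::runif(1) < 0.5
    w <- exposure_window(d, n, inc)
    expect_equal(as.integer(w[2] - w[1]) + 1L, n)
    if (!inc) expect_lt(w[2], d)
  }
})

test_that("weekly counts link by (region, ISO week) and are idempotent", {
  x <- weekly_fixture_graph()
  g <- link_weekly_counts(x$g, agent = "tester", clock = logical_clock())
  pats <- x$bundle$tables$patients
  ans_reg <- x$bundle$answers$region
  wk <- x$bundle$tables$weekly_counts
  for (i in seq_len(nrow(pats))) {
    p_iri <- paste0("http://data.avert.ie/patient/", pats$PatientID[i])
    week <- format_iso_week(iso_week_of(
      normalize_date(pats$DiagnosisDate[i])))
    rid <- sub("http://data.avert.ie/region/", "",
               ans_reg$region_iri[i], fixed = TRUE)
    want <- wk$Count[wk$RegionID == rid & wk$ISOWeek == week]
    got <- match_pattern(g, p_iri, "avert:diagnosisWeekCount", "?n")
    if (length(want) == 1L) {
      expect_equal(term_value(got$n), want)
    } else {
      expect_equal(nrow(got), 0L)
    }
  }
  # a patient whose (region, week) has no record gains nothing
  g2 <- add_triple(x$g, "http://data.avert.ie/patient/late", "rdf:type",
                   "avert:Patient")
  g2 <- add_triple(g2, "http://data.avert.ie/patient/late",
                   "avert:withinRegion", ans_reg$region_iri[1])
  g2 <- add_triple(g2, "http://data.avert.ie/patient/late",
                   "avert:diagnosisDate",
                   typed_literal("2019-06-01", "xsd:date"))
  g2 <- link_weekly_counts(g2, agent = "tester", clock = logical_clock())
  expect_equal(nrow(match_pattern(g2, "http://data.avert.ie/patient/late",
                                  "avert:diagnosisWeekCount", "?n")), 0L)
  # idempotent modulo the fresh activity record (4 core + 2 used + 1 gen)
  g3 <- link_weekly_counts(g, agent = "tester", clock = logical_clock())
  expect_equal(graph_size(g3) - graph_size(g), 7L)
})

test_that("duplicate weekly count records are a data error", {
  x <- weekly_fixture_graph()
  g <- add_triple(x$g, "http://data.avert.ie/weekly_count/dup",
                  "rdf:type", "avert:WeeklyCount")
  wk1 <- match_pattern(x$g, "?c", "rdf:type", "avert:WeeklyCount")
  first <- term_value(wk1$c[1])
  r <- match_pattern(x$g, first, "avert:region", "?r")
  w <- match_pattern(x$g, first, "avert:isoWeek", "?w")
  g <- add_triple(g, "http://data.avert.ie/weekly_count/dup",
                  "avert:region", term_value(r$r[1]))
  g <- add_triple(g, "http://data.avert.ie/weekly_count/dup",
                  "avert:isoWeek", typed_literal(term_value(w$w[1])))
  g <- add_triple(g, "http://data.avert.ie/weekly_count/dup",
                  "avert:count", typed_literal("1", "xsd:integer"))
  expect_error(link_weekly_counts(g, agent = "tester",
                                  clock = logical_clock()),
               "duplicate weekly count")
})
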