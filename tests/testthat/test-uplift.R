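# Table -> graph uplift: value transforms, term templates, mapping
# execution counting identities, and gridded-field subsetting.

test_that("dates normalize to calendar-valid yyyy-MM-dd", {
  expect_equal(normalize_date("20-10-1985", "dd-MM-yyyy"), "1985-10-20")
  expect_equal(normalize_date("01-01-2000", "dd-MM-yyyy"), "2000-01-01")
  expect_equal(normalize_date("29-02-2016", "dd-MM-yyyy"), "2016-02-29")
  expect_error(normalize_date("31-02-2015", "dd-MM-yyyy"), "31-02-2015")
  expect_error(normalize_date("29-02-2015", "dd-MM-yyyy"), "invalid")
  expect_error(normalize_date("1985-10-20", "yy/mm"), "unsupported")
})

test_that("codebook decoding maps codes and honours the unmapped policy", {
  cb <- c("0" = "Female", "1" = "Male")
  expect_equal(decode_code("0", cb), "Female")
  expect_equal(decode_code("1", cb), "Male")
  expect_error(decode_code("9", cb, column = "Gender"), "Gender")
  expect_equal(decode_code("9", cb, unmapped = "passthrough"), "9")
  expect_error(decode_code("0", c()), "empty")
})

test_that("IRI templates percent-encode substituted values per RFC 3986", {
  tpl <- term_template("http://data.avert.ie/weather_station/{name}",
                       term_kind = "iri")
  t <- apply_template(tpl,
                      list(name = "Mullingar Automatic Weather Station (AWS)"))
  expect_equal(t$value,
               paste0("http://data.avert.ie/weather_station/",
                      "Mullingar%20Automatic%20Weather%20Station%20(AWS)"))
  # spaces become %20, parentheses are kept, non-ASCII is UTF-8 encoded
  expect_equal(percent_encode("a/b"), "a%2Fb")
  expect_equal(percent_encode("é"), "%C3%A9")
})

test_that("literal templates attach datatypes and apply transforms", {
  lat <- apply_template(term_template("{lat}", datatype = "xsd:double"),
                        list(lat = "53.53722222"))
  expect_equal(lat$lexical, "53.53722222")
  expect_equal(lat$datatype, "http://www.w3.org/2001/XMLSchema#double")

  dob <- apply_template(
    term_template("{DOB}", transform = list(kind = "date",
                                            pattern = "dd-MM-yyyy")),
    list(DOB = "20-10-1985"))
  expect_equal(dob$lexical, "1985-10-20")
  expect_equal(dob$datatype, "http://www.w3.org/2001/XMLSchema#date")

  # empty cell -> no term
  expect_null(apply_template(term_template("{Gender}"),
                             list(Gender = "")))
  # unknown column -> mapping error
  expect_error(apply_template(term_template("{Missing}"),
                              list(Gender = "0")),
               "Missing")
})

station_map <- function() {
  triples_map(
    source = "stations",
    subject = term_template("http://data.avert.ie/weather_station/{name}",
                            term_kind = "iri"),
    types = c("avert:WeatherStation", "geo:Feature"),
    predicate_objects = list(
      list(predicate = "rdfs:label", object = term_template("{name}")),
      list(predicate = "geo:asWKT",
           object = term_template("POINT ({lon} {lat})",
                                  datatype = "geo:wktLiteral"))))
}

test_that("mapping execution emits types + non-missing object maps", {
  tabs <- list(stations = data.frame(
    name = "Mullingar Automatic Weather Station (AWS)",
    lon = "-7.362222222", lat = "53.53722222", stringsAsFactors = FALSE))
  g <- execute_mapping(station_map(), tabs)
  expect_equal(graph_size(g), 4L)  # 2 types + 2 object maps
  wkt <- match_pattern(g, "?s", "geo:asWKT", "?o")
  p <- parse_wkt_point(term_value(wkt$o))
  expect_identical(p$lon, -7.362222222)
  expect_identical(p$lat, 53.53722222)

  # empty table -> empty graph
  g0 <- execute_mapping(station_map(),
                        list(stations = tabs$stations[0, , drop = FALSE]))
  expect_equal(graph_size(g0), 0L)
  expect_error(execute_mapping(station_map(), list()), "stations")
})

patient_map <- function() {
  pos <- lapply(c("a", "b", "c", "d", "e"), function(col) {
    list(predicate = paste0("avert:", col),
         object = term_template(paste0("{", col, "}")))
  })
  triples_map(source = "patients",
              subject = term_template("http://data.avert.ie/patient/{id}",
                                      term_kind = "iri"),
              types = "avert:Patient", predicate_objects = pos)
}

test_that("triple counts follow the counting identity with missing cells", {
  # 10 rows, 1 type + 5 object maps, 3 missing cells -> 57 triples
  set.seed(5)
  tab <- data.frame(id = sprintf("p%02d", 1:10),
                    a = letters[1:10], b = LETTERS[1:10],
                    c = as.character(1:10), d = letters[11:20],
                    e = LETTERS[11:20], stringsAsFactors = FALSE)
  blank <- cbind(sample(10, 3), sample(2:6, 3, replace = TRUE))
  for (k in 1:3) tab[blank[k, 1], blank[k, 2]] <- ""
  n_missing <- sum(tab[, -1] == "")
  expect_equal(n_missing, 3L)
  g <- execute_mapping(patient_map(), list(patients = tab))
  expect_equal(graph_size(g), 10L * (1L + 5L) - 3L)
})

test_that("the counting identity holds on randomized tables", {
  set.seed(11)
  for (trial in seq_len(500)) {
    n <- sample(1:8, 1)
    tab <- data.frame(id = sprintf("r%03d", seq_len(n)),
                      a = sprintf("a%03d", seq_len(n)),
                      b = sprintf("b%03d", seq_len(n)),
                      c = sprintf("c%03d", seq_len(n)),
                      d = sprintf("d%03d", seq_len(n)),
                      e = sprintf("e%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
    miss <- matrix(stats::runif(n * 5) < 0.2, nrow = n)
    for (j in 1:5) tab[[j + 1L]][miss[, j]] <- ""
    g <- execute_mapping(patient_map(), list(patients = tab))
    expect_equal(graph_size(g), n * 6L - sum(miss))
  }
})

test_that("uplift is idempotent under set semantics", {
  tabs <- list(stations = data.frame(name = c("S1", "S2"),
                                     lon = c("-7", "-8"),
                                     lat = c("53", "54"),
                                     stringsAsFactors = FALSE))
  g1 <- execute_mapping(station_map(), tabs)
  g2 <- execute_mapping(station_map(), tabs, graph = g1)
  expect_true(graphs_equal(g1, g2))
})

test_that("every emitted xsd:date literal is calendar-valid yyyy-MM-dd", {
  bundle <- generate_fixtures(synthetic_config(seed = 2, n_patients = 8,
                                               n_stations = 3))
  g <- execute_mapping(default_mapping(), bundle$tables)
  tr <- g$triples
  dates <- tr$object[!is.na(tr$datatype) &
                       grepl("#date$", tr$datatype)]
  expect_gt(length(dates), 0L)
  expect_true(all(grepl("^\\d{4}-\\d{2}-\\d{2}$", dates)))
  expect_true(all(!is.na(as.Date(dates))))
})

test_that("grid subsetting returns one row per in-box cell-centre", {
  dates <- seq(as.Date("2015-01-01"), by = "day", length.out = 10)
  lats <- seq(51, 55.5, length.out = 10)
  lons <- seq(-11, -5, length.out = 10)
  set.seed(3)
  f <- gridded_field(dates, lats, lons,
                     array(stats::rnorm(1000), dim = c(10, 10, 10)),
                     "pm10", "ug/m3")

  # closed bbox covering 3 lats x 4 lons, 5 dates -> 60 rows
  bbox <- c(lons[3], lons[6], lats[2], lats[4])
  tab <- subset_grid(f, bbox, c(dates[2], dates[6]))
  expect_equal(nrow(tab), 5L * 3L * 4L)
  expect_equal(names(tab), c("date", "lat", "lon", "pm10"))

  # full cover
  expect_equal(nrow(subset_grid(f, c(-11, -5, 51, 55.5),
                                range(dates))), 1000L)
  # bbox west of all cells -> empty, not an error
  expect_equal(nrow(subset_grid(f, c(-30, -20, 51, 55.5), range(dates))),
               0L)
  expect_error(subset_grid(f, c(-5, -11, 51, 55.5), range(dates)),
               "bbox")
})

test_that("grid subset row counts match a brute-force cell filter", {
  set.seed(21)
  for (trial in seq_len(500)) {
    nd <- sample(2:6, 1); nla <- sample(2:6, 1); nlo <- sample(2:6, 1)
    dates <- seq(as.Date("2015-01-01"), by = "day", length.out = nd)
    lats <- sort(stats::runif(nla, 51, 55)); lons <- sort(stats::runif(nlo, -11, -5))
    f <- gridded_field(dates, lats, lons,
                       array(seq_len(nd * nla * nlo),
                             dim = c(nd, nla, nlo)), "v")
    b <- c(sort(stats::runif(2, -11, -5)), sort(stats::runif(2, 51, 55)))
    dr <- sort(sample(dates, 2))
    tab <- subset_grid(f, b, dr)
    # brute force over all (t, lat, lon) cells
    cnt <- 0L
    for (t in seq_len(nd)) for (i in seq_len(nla)) for (j in seq_len(nlo)) {
      if (dates[t] >= dr[1] && dates[t] <= dr[2] &&
          lats[i] >= b[3] && lats[i] <= b[4] &&
          lons[j] >= b[1] && lons[j] <= b[2]) cnt <- cnt + 1L
    }
    expect_equal(nrow(tab), cnt)
  }
})

test_that("gridded fields round-trip through the long-format CSV", {
  set.seed(8)
  dates <- seq(as.Date("2015-01-01"), by = "day", length.out = 4)
  f <- gridded_field(dates, c(51, 52), c(-7, -6),
                     array(round(stats::rnorm(16), 3), dim = c(4, 2, 2)),
                     "pm10", "ug/m3")
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(f, path)
  f2 <- read_grid_csv(path)
  expect_equal(f2$values, f$values)
  expect_equal(f2$variable_name, "pm10")
  expect_equal(f2$units, "ug/m3")
})
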