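# Seeded synthetic-data generator emulating the shapes of the source
# datasets: a small patient table with townland-centroid coordinates and
# coded fields, weather stations with daily observation series, weekly
# regional infection counts derived from a hidden daily incidence series,
# a gridded pollution field, and a set of non-overlapping boundary polygons
# tiling a lon/lat rectangle near Ireland's bounds. Ground-truth answer
# tables (true nearest station, true region, true window means) are
# computed by brute force at generation time so every enrichment step can
# be scored for exact recovery.

FIXTURE_BOUNDS <- c(lon_min = -11, lon_max = -5, lat_min = 51,
                    lat_max = 55.5)

#' Configuration for the synthetic fixture generator
#'
#' Defaults describe a small but fully featured study: a rare-disease-scale
#' cohort of 20 patients over a 90-day span, 12 weather stations with daily
#' observations, 6 county-scale reporting regions with weekly counts, a
#' 10 x 10 daily pollution grid, and 5% missingness in observation values.
#'
#' @param seed Integer RNG seed; identical seeds give byte-identical
#'   bundles.
#' @param n_regions,n_stations,n_patients Entity counts (>= 1).
#' @param date_start,date_end Observation span (>= 14 days).
#' @param n_lat,n_lon Grid dimensions for the gridded field.
#' @param missing_rate Probability in `[0, 1)` that an observation value
#'   cell is blanked. Missingness touches values only, never keys.
#' @param window_days Exposure-window length used for the ground-truth
#'   window means.
#' @param n_region_rows,n_region_cols Optional explicit region tiling;
#'   must multiply to `n_regions`.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(seed = 1L, n_regions = 6L, n_stations = 12L,
                             n_patients = 20L, date_start = "2015-01-01",
                             date_end = "2015-03-31", n_lat = 10L,
                             n_lon = 10L, missing_rate = 0.05,
                             window_days = 7L, n_region_rows = NULL,
                             n_region_cols = NULL) {
  stopifnot(n_regions >= 1, n_stations >= 1, n_patients >= 1,
            missing_rate >= 0, missing_rate < 1, window_days >= 1)
  span <- as.integer(as.Date(date_end) - as.Date(date_start)) + 1L
  if (span < 14L) stop("date span must cover at least 14 days",
                       call. = FALSE)
  if (!is.null(n_region_rows) || !is.null(n_region_cols)) {
    if (is.null(n_region_rows) || is.null(n_region_cols) ||
        n_region_rows * n_region_cols != n_regions) {
      stop("infeasible region tiling: n_region_rows * n_region_cols must ",
           "equal n_regions", call. = FALSE)
    }
  }
  structure(list(seed = as.integer(seed), n_regions = as.integer(n_regions),
                 n_stations = as.integer(n_stations),
                 n_patients = as.integer(n_patients),
                 date_start = as.Date(date_start),
                 date_end = as.Date(date_end),
                 n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
                 missing_rate = missing_rate,
                 window_days = as.integer(window_days),
                 n_region_rows = n_region_rows,
                 n_region_cols = n_region_cols,
                 codebooks = list(
                   gender = c("0" = "Female", "1" = "Male"),
                   comorbidity = c("0" = "absent", "1" = "present"))),
            class = "synthetic_config")
}

region_tiling <- function(config) {
  n <- config$n_regions
  if (!is.null(config$n_region_rows)) {
    return(c(rows = config$n_region_rows, cols = config$n_region_cols))
  }
  rows <- floor(sqrt(n))
  while (n %% rows != 0L) rows <- rows - 1L
  c(rows = rows, cols = n %/% rows)
}

fmt_coord <- function(x) sprintf("%.6f", x)
fmt_val <- function(x) sprintf("%.2f", x)
fmt_dmy <- function(d) format(d, "%d-%m-%Y")

#' Generate a synthetic fixture bundle
#'
#' Regions tile the bounding rectangle with no overlap; every patient
#' point lies strictly inside exactly one region (interior margin); daily
#' station observations follow a seasonal sinusoid plus seeded noise with
#' value cells blanked at `missing_rate`; weekly regional counts are the
#' ISO-week sums of a hidden seeded daily incidence series; gender and
#' comorbidity are emitted as 0/1 codes and all dates as `dd-MM-yyyy`, so
#' uplift must exercise decoding and date normalization.
#'
#' @param config A [synthetic_config()].
#' @return A list with `tables` (named character-column data.frames:
#'   `patients`, `stations`, `regions`, `observations`, `weekly_counts`),
#'   `grid` (a [gridded_field()]), `answers` (ground-truth data.frames:
#'   `nearest_station`, `region`, `window_means`, `daily_incidence`) and
#'   the `config`.
#' @export
generate_fixtures <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  b <- FIXTURE_BOUNDS
  dates <- seq(config$date_start, config$date_end, by = "day")

  # --- regions: grid tiling of the rectangle -------------------------------
  tl <- region_tiling(config)
  lon_edges <- seq(b["lon_min"], b["lon_max"], length.out = tl["cols"] + 1L)
  lat_edges <- seq(b["lat_min"], b["lat_max"], length.out = tl["rows"] + 1L)
  reg_rows <- list()
  reg_cells <- list()
  k <- 0L
  for (i in seq_len(tl["rows"])) {
    for (j in seq_len(tl["cols"])) {
      k <- k + 1L
      id <- sprintf("R%02d", k)
      lo <- c(lon_edges[j], lon_edges[j + 1L])
      la <- c(lat_edges[i], lat_edges[i + 1L])
      poly <- ring_polygon(c(lo[1], lo[2], lo[2], lo[1]),
                           c(la[1], la[1], la[2], la[2]))
      reg_rows[[k]] <- data.frame(
        RegionID = id, Label = sprintf("Health Area %02d", k),
        Level = "lho", WKT = format_wkt_polygon(poly),
        stringsAsFactors = FALSE)
      reg_cells[[k]] <- list(id = id, lon = lo, lat = la)
    }
  }
  regions_tab <- do.call(rbind, reg_rows)

  # --- stations ------------------------------------------------------------
  st_lon <- stats::runif(config$n_stations, b["lon_min"], b["lon_max"])
  st_lat <- stats::runif(config$n_stations, b["lat_min"], b["lat_max"])
  st_name <- sprintf("Synthetic Station %02d (AWS)",
                     seq_len(config$n_stations))
  stations_tab <- data.frame(name = st_name, lon = fmt_coord(st_lon),
                             lat = fmt_coord(st_lat),
                             stringsAsFactors = FALSE)

  # --- patients (strictly inside one region, margin 5% of cell) ------------
  reg_idx <- sample.int(config$n_regions, config$n_patients, replace = TRUE)
  p_lon <- numeric(config$n_patients)
  p_lat <- numeric(config$n_patients)
  for (i in seq_len(config$n_patients)) {
    cell <- reg_cells[[reg_idx[i]]]
    mlon <- diff(cell$lon) * 0.05
    mlat <- diff(cell$lat) * 0.05
    p_lon[i] <- stats::runif(1, cell$lon[1] + mlon, cell$lon[2] - mlon)
    p_lat[i] <- stats::runif(1, cell$lat[1] + mlat, cell$lat[2] - mlat)
  }
  # diagnosis late enough that the exposure window lies inside the span
  diag_dates <- config$date_start + config$window_days +
    sample.int(length(dates) - config$window_days, config$n_patients,
               replace = TRUE) - 1L
  dob <- as.Date("1990-01-01") +
    sample.int(9000L, config$n_patients, replace = TRUE) - 1L
  patients_tab <- data.frame(
    PatientID = sprintf("P%03d", seq_len(config$n_patients)),
    DOB = fmt_dmy(dob), DiagnosisDate = fmt_dmy(diag_dates),
    Gender = as.character(sample(0:1, config$n_patients, replace = TRUE)),
    Comorbidity = as.character(stats::rbinom(config$n_patients, 1, 0.3)),
    Lon = fmt_coord(p_lon), Lat = fmt_coord(p_lat),
    stringsAsFactors = FALSE)

  # --- daily observations: seasonal sinusoid + noise, value-only gaps ------
  nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  obs_list <- vector("list", config$n_stations)
  for (s in seq_len(config$n_stations)) {
    temp <- 9 + 6 * sin(2 * pi * (doy - 105) / 365.25) +
      stats::rnorm(nd, 0, 1.5)
    rain <- round(pmax(0, stats::rnorm(nd, 2, 3)), 2)
    temp_s <- fmt_val(temp)
    rain_s <- fmt_val(rain)
    temp_s[stats::runif(nd) < config$missing_rate] <- ""
    rain_s[stats::runif(nd) < config$missing_rate] <- ""
    obs_list[[s]] <- data.frame(Station = st_name[s], Date = fmt_dmy(dates),
                                TemperatureC = temp_s, RainfallMm = rain_s,
                                stringsAsFactors = FALSE)
  }
  observations_tab <- do.call(rbind, obs_list)
  rownames(observations_tab) <- NULL

  # --- hidden daily incidence and derived weekly counts --------------------
  inc <- expand.grid(RegionID = regions_tab$RegionID,
                     Date = format(dates, "%Y-%m-%d"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  inc <- inc[order(inc$RegionID, inc$Date), , drop = FALSE]
  inc$Cases <- stats::rpois(nrow(inc), lambda = 3)
  inc$ISOWeek <- vapply(inc$Date,
                        function(d) format_iso_week(iso_week_of(d)),
                        character(1), USE.NAMES = FALSE)
  wk <- stats::aggregate(Cases ~ RegionID + ISOWeek, data = inc, FUN = sum)
  wk <- wk[order(wk$RegionID, wk$ISOWeek), , drop = FALSE]
  weekly_tab <- data.frame(RegionID = wk$RegionID, ISOWeek = wk$ISOWeek,
                           Count = as.character(wk$Cases),
                           stringsAsFactors = FALSE)
  rownames(weekly_tab) <- NULL

  # --- gridded pollution field ---------------------------------------------
  g_lat <- seq(b["lat_min"], b["lat_max"], length.out = config$n_lat)
  g_lon <- seq(b["lon_min"], b["lon_max"], length.out = config$n_lon)
  vals <- array(
    round(20 + 8 * sin(2 * pi * (rep(doy, config$n_lat * config$n_lon)) /
                         365.25) +
            stats::rnorm(nd * config$n_lat * config$n_lon, 0, 2), 3),
    dim = c(nd, config$n_lat, config$n_lon))
  grid <- gridded_field(dates, g_lat, g_lon, vals,
                        variable_name = "pm10", units = "ug/m3")

  # --- ground-truth answers (brute force, straight from the tables) --------
  st_iri <- paste0("http://data.avert.ie/weather_station/",
                   percent_encode(st_name))
  st_lon_r <- as.numeric(stations_tab$lon)
  st_lat_r <- as.numeric(stations_tab$lat)
  p_lon_r <- as.numeric(patients_tab$Lon)
  p_lat_r <- as.numeric(patients_tab$Lat)
  ns_iri <- character(config$n_patients)
  ns_km <- numeric(config$n_patients)
  for (i in seq_len(config$n_patients)) {
    d <- haversine_km_lonlat(p_lon_r[i], p_lat_r[i], st_lon_r, st_lat_r)
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[order(st_iri[best])][1]
    ns_iri[i] <- st_iri[best]
    ns_km[i] <- d[best]
  }
  answers_nearest <- data.frame(PatientID = patients_tab$PatientID,
                                station_iri = ns_iri,
                                distance_km = vapply(ns_km, shortest_decimal,
                                                     character(1)),
                                stringsAsFactors = FALSE)
  answers_region <- data.frame(
    PatientID = patients_tab$PatientID,
    region_iri = paste0("http://data.avert.ie/region/",
                        regions_tab$RegionID[reg_idx]),
    stringsAsFactors = FALSE)

  win_mean <- character(config$n_patients)
  for (i in seq_len(config$n_patients)) {
    win <- exposure_window(diag_dates[i], config$window_days)
    ns_name <- st_name[match(ns_iri[i], st_iri)]
    obs <- observations_tab[observations_tab$Station == ns_name, ,
                            drop = FALSE]
    od <- as.Date(obs$Date, format = "%d-%m-%Y")
    vals_i <- obs$TemperatureC[od >= win[1] & od <= win[2]]
    x <- suppressWarnings(as.numeric(vals_i[nzchar(vals_i)]))
    win_mean[i] <- if (length(x) == 0L) "" else shortest_decimal(mean(x))
  }
  answers_window <- data.frame(PatientID = patients_tab$PatientID,
                               mean_temperature = win_mean,
                               stringsAsFactors = FALSE)

  list(tables = list(patients = patients_tab, stations = stations_tab,
                     regions = regions_tab,
                     observations = observations_tab,
                     weekly_counts = weekly_tab),
       grid = grid,
       answers = list(nearest_station = answers_nearest,
                      region = answers_region,
                      window_means = answers_window,
                      daily_incidence = inc[, c("RegionID", "Date",
                                                "Cases")]),
       config = config)
}

#' Write a fixture bundle to disk
#'
#' Emits one CSV per logical table, a long-format CSV for the gridded
#' field, and the ground-truth answer tables under `answers/`. Output is
#' byte-deterministic for a given config.
#'
#' @param bundle Result of [generate_fixtures()].
#' @param dir Target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(bundle, dir) {
  dir.create(file.path(dir, "answers"), recursive = TRUE,
             showWarnings = FALSE)
  for (nm in names(bundle$tables)) {
    write_enriched_csv(bundle$tables[[nm]],
                       file.path(dir, paste0(nm, ".csv")))
  }
  write_grid_csv(bundle$grid, file.path(dir, "grid_pm10.csv"))
  for (nm in names(bundle$answers)) {
    write_enriched_csv(bundle$answers[[nm]],
                       file.path(dir, "answers", paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Read fixture tables back from a directory
#' @param dir Directory written by [write_fixtures()].
#' @return Named list of all-character data.frames.
#' @export
read_fixture_tables <- function(dir) {
  nms <- c("patients", "stations", "regions", "observations",
           "weekly_counts")
  out <- lapply(nms, function(nm) {
    df <- read_enriched_csv(file.path(dir, paste0(nm, ".csv")))
    for (j in seq_along(df)) df[[j]][is.na(df[[j]])] <- ""
    df
  })
  names(out) <- nms
  out
}
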