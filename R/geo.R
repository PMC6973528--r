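# WGS84 point/polygon geometry: WKT parsing (longitude-first, CRS84 axis
# order), great-circle distance, planar even-odd containment, nearest-station
# search, and materialization of the spatial-enrichment triples.

EARTH_RADIUS_KM <- 6371.0088  # IUGG mean Earth radius

#' Construct a WGS84 point (longitude-first)
#'
#' @param lon Degrees east, in `[-180, 180]`.
#' @param lat Degrees north, in `[-90, 90]`.
#' @param lon_lex,lat_lex Optional original lexical forms, preserved by
#'   [format_wkt_point()] so parse/format round trips keep full input
#'   precision.
#' @return A `wkt_point` object.
#' @export
wkt_point <- function(lon, lat, lon_lex = NULL, lat_lex = NULL) {
  stopifnot(is.numeric(lon), is.numeric(lat))
  if (lon < -180 || lon > 180) {
    stop("longitude out of bounds [-180, 180]: ", lon, call. = FALSE)
  }
  if (lat < -90 || lat > 90) {
    stop("latitude out of bounds [-90, 90]: ", lat, call. = FALSE)
  }
  structure(list(lon = lon, lat = lat,
                 lon_lex = lon_lex %||% shortest_decimal(lon),
                 lat_lex = lat_lex %||% shortest_decimal(lat)),
            class = "wkt_point")
}

# shortest decimal representation that round-trips the double
shortest_decimal <- function(x) {
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g")
    if (as.numeric(s) == x) return(s)
  }
  as.character(x)
}

#' Parse / format a WKT POINT literal
#'
#' Accepts `"POINT (lon lat)"` with an optional leading `<CRS>` IRI; only
#' the CRS84 (WGS84 lon-lat) reference system is supported — an explicit
#' different CRS is rejected. Formatting emits `"POINT (lon lat)"` with the
#' original input precision, so `format(parse(t)) == t` for canonical `t`.
#'
#' @param text WKT text.
#' @return `parse_wkt_point`: a [wkt_point()]; `format_wkt_point`: text.
#' @export
#' @examples
#' parse_wkt_point("POINT (-7.362222222 53.53722222)")
parse_wkt_point <- function(text) {
  re <- paste0("^\\s*(<([^>]*)>\\s+)?POINT\\s*\\(\\s*",
               "([-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?)\\s+",
               "([-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?)\\s*\\)\\s*$")
  m <- regmatches(text, regexec(re, text))[[1]]
  if (length(m) == 0L) {
    stop("text does not match the POINT grammar: ", dQuote(text),
         call. = FALSE)
  }
  crs <- m[3]
  if (nzchar(crs) &&
      !grepl("CRS84|4326$", crs)) {
    stop("unsupported CRS: ", crs, " (only WGS84/CRS84 is accepted)",
         call. = FALSE)
  }
  p <- wkt_point(as.numeric(m[4]), as.numeric(m[6]),
                 lon_lex = m[4], lat_lex = m[6])
  attr(p, "crs") <- if (nzchar(crs)) crs else NULL
  p
}

#' @rdname parse_wkt_point
#' @param p A [wkt_point()].
#' @export
format_wkt_point <- function(p) {
  stopifnot(inherits(p, "wkt_point"))
  paste0("POINT (", p$lon_lex, " ", p$lat_lex, ")")
}

#' @export
print.wkt_point <- function(x, ...) {
  cat(format_wkt_point(x), "\n")
  invisible(x)
}

#' Great-circle distance (haversine) in kilometres
#'
#' Uses the haversine formula on a sphere of radius 6371.0088 km (the IUGG
#' mean Earth radius):
#' `d = 2R asin(sqrt(sin^2(dphi/2) + cos(phi1) cos(phi2) sin^2(dlambda/2)))`.
#' Symmetric and non-negative by construction. Vectorised over coordinate
#' vectors via the `*_lonlat` form.
#'
#' @param a,b [wkt_point()] objects.
#' @return Distance in km.
#' @export
#' @examples
#' haversine_km(wkt_point(0, 0), wkt_point(90, 0))  # quarter great circle
haversine_km <- function(a, b) {
  stopifnot(inherits(a, "wkt_point"), inherits(b, "wkt_point"))
  haversine_km_lonlat(a$lon, a$lat, b$lon, b$lat)
}

#' @rdname haversine_km
#' @param lon1,lat1,lon2,lat2 Numeric degree vectors (recycled).
#' @export
haversine_km_lonlat <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  h <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(h)))
}

# --- polygons ---------------------------------------------------------------

segments_intersect <- function(p1, p2, p3, p4) {
  # proper intersection test for the self-intersection check
  d <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Construct a simple ring polygon
#'
#' Vertices are stored open (first != last); the ring is closed implicitly.
#' Construction rejects rings with fewer than three vertices, repeated
#' consecutive vertices, zero area, or self-intersecting edges.
#'
#' @param lon,lat Numeric degree vectors of equal length (>= 3).
#' @return A `ring_polygon` object.
#' @export
ring_polygon <- function(lon, lat) {
  stopifnot(length(lon) == length(lat))
  n <- length(lon)
  if (n >= 2L && lon[1] == lon[n] && lat[1] == lat[n]) {
    lon <- lon[-n]; lat <- lat[-n]; n <- n - 1L
  }
  if (n < 3L) stop("a ring polygon needs at least 3 vertices", call. = FALSE)
  pts <- cbind(lon, lat)
  nxt <- c(2:n, 1L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i || j == nxt[i] || nxt[j] == i) next  # shared endpoints
      if (segments_intersect(pts[i, ], pts[nxt[i], ],
                             pts[j, ], pts[nxt[j], ])) {
        stop("self-intersecting polygon (edges ", i, " and ", j, ")",
             call. = FALSE)
      }
    }
  }
  # shoelace area; zero means degenerate (checked after the edge test so a
  # crossed ring is reported as self-intersecting, not zero-area)
  area2 <- sum(lon * c(lat[-1], lat[1]) - c(lon[-1], lon[1]) * lat)
  if (abs(area2) < 1e-12) {
    stop("degenerate polygon (zero area)", call. = FALSE)
  }
  structure(list(lon = lon, lat = lat), class = "ring_polygon")
}

#' Parse / format a WKT POLYGON (single exterior ring)
#' @param text WKT text `"POLYGON ((lon lat, lon lat, ...))"`.
#' @return `parse_wkt_polygon`: a [ring_polygon()]; `format_wkt_polygon`:
#'   WKT text with an explicitly closed ring.
#' @export
parse_wkt_polygon <- function(text) {
  m <- regmatches(text,
                  regexec("^\\s*POLYGON\\s*\\(\\(\\s*(.*?)\\s*\\)\\)\\s*$",
                          text))[[1]]
  if (length(m) == 0L) {
    stop("text does not match the POLYGON grammar", call. = FALSE)
  }
  pairs <- strsplit(trimws(strsplit(m[2], ",")[[1]]), "\\s+")
  lon <- vapply(pairs, function(p) as.numeric(p[1]), numeric(1))
  lat <- vapply(pairs, function(p) as.numeric(p[2]), numeric(1))
  if (anyNA(lon) || anyNA(lat)) stop("malformed POLYGON text", call. = FALSE)
  ring_polygon(lon, lat)
}

#' @rdname parse_wkt_polygon
#' @param poly A [ring_polygon()].
#' @export
format_wkt_polygon <- function(poly) {
  lon <- c(poly$lon, poly$lon[1])
  lat <- c(poly$lat, poly$lat[1])
  paste0("POLYGON ((",
         paste(paste(vapply(lon, shortest_decimal, character(1)),
                     vapply(lat, shortest_decimal, character(1))),
               collapse = ", "),
         "))")
}

point_on_segment <- function(px, py, ax, ay, bx, by, eps = 1e-12) {
  cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  if (abs(cross) > eps * max(1, abs(bx - ax), abs(by - ay))) return(FALSE)
  px >= min(ax, bx) - eps && px <= max(ax, bx) + eps &&
    py >= min(ay, by) - eps && py <= max(ay, by) + eps
}

#' Point-in-polygon test (even-odd rule, boundary inclusive)
#'
#' Ray casting in plate-carree (plain lon/lat) coordinates; points lying on
#' an edge or vertex count as inside. Planar treatment is appropriate at
#' the county scale this package targets, where great-circle curvature
#' across a polygon is negligible.
#'
#' @param p A [wkt_point()].
#' @param poly A [ring_polygon()].
#' @return Logical scalar.
#' @export
point_in_polygon <- function(p, poly) {
  stopifnot(inherits(p, "wkt_point"), inherits(poly, "ring_polygon"))
  x <- p$lon; y <- p$lat
  vx <- poly$lon; vy <- poly$lat
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (point_on_segment(x, y, vx[j], vy[j], vx[i], vy[i])) return(TRUE)
    if ((vy[i] > y) != (vy[j] > y)) {
      xint <- vx[i] + (y - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Construct a named region backed by a polygon
#'
#' @param id Region IRI (string or [iri()]).
#' @param label Human-readable label.
#' @param polygon A [ring_polygon()].
#' @param level Administrative level: `"county"`, `"electoral_division"`,
#'   `"townland"` or `"lho"`.
#' @return A `region` object.
#' @export
region <- function(id, label, polygon,
                   level = c("county", "electoral_division", "townland",
                             "lho")) {
  level <- match.arg(level)
  id <- if (inherits(id, "tl_term")) id$value else iri(id)$value
  stopifnot(inherits(polygon, "ring_polygon"))
  structure(list(id = id, label = label, polygon = polygon, level = level),
            class = "region")
}

#' Find the region containing a point
#'
#' Regions are expected to be mutually non-overlapping at one level; a
#' point contained by more than one region raises an ambiguity error
#' (boundary points shared between adjacent tiles are resolved to the
#' first containing region only when the others do not also claim the
#' point's interior side — with boundary-inclusive containment, a point
#' exactly on a shared border is reported ambiguous).
#'
#' @param p A [wkt_point()].
#' @param regions List of [region()] objects.
#' @return The containing `region`, or `NULL` if outside all of them.
#' @export
assign_region <- function(p, regions) {
  hits <- which(vapply(regions, function(r) point_in_polygon(p, r$polygon),
                       logical(1)))
  if (length(hits) == 0L) return(NULL)
  if (length(hits) > 1L) {
    ids <- vapply(regions[hits], `[[`, character(1), "id")
    stop("ambiguous region assignment: point lies in ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  regions[[hits]]
}

#' Nearest weather station by great-circle distance
#'
#' Exhaustive scan over the station list; ties broken by lexicographically
#' smallest station IRI so results are deterministic and auditable.
#'
#' @param p A [wkt_point()].
#' @param stations data.frame with columns `iri`, `lon`, `lat` (or a list
#'   of `list(iri=, point=)` pairs).
#' @return `list(iri = <station IRI>, distance_km = <numeric>)`.
#' @export
nearest_station <- function(p, stations) {
  stopifnot(inherits(p, "wkt_point"))
  if (is.data.frame(stations)) {
    df <- stations
  } else {
    df <- data.frame(
      iri = vapply(stations, `[[`, character(1), "iri"),
      lon = vapply(stations, function(s) s$point$lon, numeric(1)),
      lat = vapply(stations, function(s) s$point$lat, numeric(1)),
      stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) stop("empty station list", call. = FALSE)
  d <- haversine_km_lonlat(p$lon, p$lat, df$lon, df$lat)
  best <- which(d == min(d))
  if (length(best) > 1L) {
    best <- best[order(df$iri[best], method = "radix")][1]
  }
  list(iri = df$iri[best], distance_km = d[best])
}

# --- enrichment materialization --------------------------------------------

# follow <entity> geo:hasGeometry <geom> ; <geom> geo:asWKT "..." and parse
entity_points <- function(graph, entities) {
  out <- data.frame(iri = character(0), lon = numeric(0), lat = numeric(0),
                    stringsAsFactors = FALSE)
  for (e in entities) {
    geom <- match_pattern(graph, e, "geo:hasGeometry", "?g")
    if (nrow(geom) == 0L) next
    wkt <- match_pattern(graph, term_value(geom$g[1]), "geo:asWKT", "?w")
    if (nrow(wkt) == 0L) next
    p <- tryCatch(parse_wkt_point(term_value(wkt$w[1])),
                  error = function(e) NULL)
    if (is.null(p)) next
    out <- rbind(out, data.frame(iri = e, lon = p$lon, lat = p$lat,
                                 stringsAsFactors = FALSE))
  }
  out
}

graph_regions <- function(graph) {
  rs <- match_pattern(graph, "?r", "rdf:type", "avert:Region")
  regions <- list()
  for (r in term_value(rs$r)) {
    geom <- match_pattern(graph, r, "geo:hasGeometry", "?g")
    if (nrow(geom) == 0L) next
    wkt <- match_pattern(graph, term_value(geom$g[1]), "geo:asWKT", "?w")
    if (nrow(wkt) == 0L) next
    lab <- match_pattern(graph, r, "rdfs:label", "?l")
    lev <- match_pattern(graph, r, "avert:level", "?v")
    poly <- tryCatch(parse_wkt_polygon(term_value(wkt$w[1])),
                     error = function(e) NULL)
    if (is.null(poly)) next
    regions[[length(regions) + 1L]] <- region(
      r,
      label = if (nrow(lab) > 0L) term_value(lab$l[1]) else r,
      polygon = poly,
      level = if (nrow(lev) > 0L) term_value(lev$v[1]) else "county")
  }
  regions
}

#' Materialize nearest-station and region-containment links
#'
#' For every patient with a resolvable geometry, adds
#' `avert:nearestStation` (IRI), `avert:nearestStationDistanceKm`
#' (xsd:double) and, when the patient falls inside a region,
#' `avert:withinRegion` (IRI) — two to three new triples per patient.
#' Patients without a geometry are skipped with a warning. The operation is
#' idempotent (set semantics) and never alters pre-existing triples. A
#' provenance activity describing the batch is recorded via
#' [record_activity()].
#'
#' @param graph A `triple_graph` holding uplifted patients, stations and
#'   regions (`rdf:type` `avert:Patient` / `avert:WeatherStation` /
#'   `avert:Region`, geometries via `geo:hasGeometry`/`geo:asWKT`).
#' @param agent Agent identifier string minted under
#'   `http://data.avert.ie/agent/`.
#' @param clock Zero-argument function returning a POSIXct timestamp for
#'   the provenance record (injectable for reproducible pipelines).
#' @return The enriched `triple_graph`.
#' @export
materialize_spatial_links <- function(graph, agent = default_agent(),
                                      clock = Sys.time) {
  pats <- match_pattern(graph, "?p", "rdf:type", "avert:Patient")
  stns <- match_pattern(graph, "?s", "rdf:type", "avert:WeatherStation")
  patients <- term_value(pats$p)
  station_pts <- entity_points(graph, term_value(stns$s))
  regions <- graph_regions(graph)
  if (nrow(station_pts) == 0L) {
    stop("no weather stations with geometry in graph", call. = FALSE)
  }
  started <- clock()
  skipped <- character(0)
  for (pt_iri in patients) {
    pp <- entity_points(graph, pt_iri)
    if (nrow(pp) == 0L) {
      skipped <- c(skipped, pt_iri)
      next
    }
    p <- wkt_point(pp$lon[1], pp$lat[1])
    ns_hit <- nearest_station(p, station_pts)
    graph <- add_triple(graph, pt_iri, "avert:nearestStation", ns_hit$iri)
    graph <- add_triple(graph, pt_iri, "avert:nearestStationDistanceKm",
                        typed_literal(shortest_decimal(ns_hit$distance_km),
                                      "xsd:double"))
    reg <- if (length(regions) > 0L) assign_region(p, regions) else NULL
    if (!is.null(reg)) {
      graph <- add_triple(graph, pt_iri, "avert:withinRegion", reg$id)
    }
  }
  if (length(skipped) > 0L) {
    warning("skipped ", length(skipped),
            " patient(s) without geometry: ",
            paste(utils::head(skipped, 3L), collapse = ", "), call. = FALSE)
  }
  act <- prov_activity(
    id = next_activity_iri(graph, "spatial-links"),
    started = started, ended = clock(), agent = agent,
    used = c("http://data.avert.ie/dataset/patients",
             "http://data.avert.ie/dataset/weather_stations",
             "http://data.avert.ie/dataset/regions"),
    generated = enrichment_batch_iris(c("nearestStation",
                                        "nearestStationDistanceKm",
                                        "withinRegion")))
  record_activity(graph, act)
}

default_agent <- function() {
  Sys.getenv("USER", unset = Sys.getenv("USERNAME", unset = "analyst"))
}
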