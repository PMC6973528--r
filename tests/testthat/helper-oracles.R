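# Shared fixtures and independent oracles for the test suite.

# --- random graph generator (seeded by caller) ------------------------------

random_iri <- function(n = 1) {
  paste0("http://example.org/", sample(c("a", "b", "c", "node", "x"), n,
                                       replace = TRUE),
         "/", sample.int(50, n, replace = TRUE))
}

random_literal <- function() {
  kind <- sample(4, 1)
  if (kind == 1L) {
    d <- as.Date("2015-01-01") + sample.int(1000, 1)
    typed_literal(format(d, "%Y-%m-%d"), "xsd:date")
  } else if (kind == 2L) {
    typed_literal(as.character(round(stats::rnorm(1), 4)), "xsd:double")
  } else if (kind == 3L) {
    typed_literal(as.character(sample.int(1000, 1)), "xsd:integer")
  } else {
    chars <- c(letters, " ", '"', "\\", "\n", "\t", "é", ",")
    typed_literal(paste(sample(chars, sample(0:12, 1), replace = TRUE),
                        collapse = ""), "xsd:string")
  }
}

random_graph <- function(n_triples) {
  g <- triple_graph()
  for (i in seq_len(n_triples)) {
    o <- if (stats::runif(1) < 0.5) iri(random_iri()) else random_literal()
    g <- add_triple(g, random_iri(), random_iri(), o)
  }
  g
}

# --- nested-loop conjunctive join oracle ------------------------------------

# bindings as a list of named character vectors (encoded terms); pattern
# positions are concrete encoded terms or "?var"
oracle_evaluate <- function(graph, patterns, projection) {
  tr <- graph$triples
  enc <- list(
    s = paste0("<", tr$subject, ">"),
    p = paste0("<", tr$predicate, ">"),
    o = mapply(function(o, k, d) {
      if (k == "iri") paste0("<", o, ">")
      else term_encode_one(o, d)
    }, tr$object, tr$object_kind, tr$datatype, USE.NAMES = FALSE))
  if (nrow(tr) == 0L) enc <- list(s = character(0), p = character(0),
                                  o = character(0))
  solutions <- list(stats::setNames(character(0), character(0)))
  for (pat in patterns) {
    new_solutions <- list()
    for (sol in solutions) {
      for (ti in seq_len(nrow(tr))) {
        ext <- sol
        ok <- TRUE
        for (pos in c("s", "p", "o")) {
          pterm <- pat[[pos]]
          tterm <- enc[[pos]][ti]
          if (startsWith(pterm, "?")) {
            v <- substring(pterm, 2L)
            if (v %in% names(ext)) {
              if (ext[[v]] != tterm) { ok <- FALSE; break }
            } else {
              ext[v] <- tterm
            }
          } else if (pterm != tterm) {
            ok <- FALSE
            break
          }
        }
        if (ok) new_solutions[[length(new_solutions) + 1L]] <- ext
      }
    }
    solutions <- new_solutions
  }
  rows <- lapply(solutions, function(s) s[projection])
  if (length(rows) == 0L) {
    out <- as.data.frame(stats::setNames(
      replicate(length(projection), character(0), simplify = FALSE),
      projection), optional = TRUE)
    return(out)
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE,
                       optional = TRUE)
  names(out) <- projection
  ord <- do.call(order, c(unname(as.list(out)), list(method = "radix")))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

term_encode_one <- function(lex, dt) {
  x <- gsub("\\", "\\\\", lex, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  paste0("\"", x, "\"^^<", dt, ">")
}

# --- winding-number point-in-polygon oracle ---------------------------------

winding_number_inside <- function(x, y, vx, vy) {
  n <- length(vx)
  ang <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(vy[i] - y, vx[i] - x)
    a2 <- atan2(vy[j] - y, vx[j] - x)
    da <- a2 - a1
    while (da > pi) da <- da - 2 * pi
    while (da < -pi) da <- da + 2 * pi
    ang <- ang + da
  }
  abs(ang) > pi  # ~2*pi inside, ~0 outside
}

dist_point_to_ring <- function(x, y, vx, vy) {
  n <- length(vx)
  d <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- vx[i]; ay <- vy[i]; bx <- vx[j]; by <- vy[j]
    len2 <- (bx - ax)^2 + (by - ay)^2
    t <- if (len2 == 0) 0 else
      max(0, min(1, ((x - ax) * (bx - ax) + (y - ay) * (by - ay)) / len2))
    d <- min(d, sqrt((x - (ax + t * (bx - ax)))^2 +
                       (y - (ay + t * (by - ay)))^2))
  }
  d
}

random_convex_polygon <- function(n_pts = 8) {
  x <- stats::runif(n_pts, -5, 5)
  y <- stats::runif(n_pts, -5, 5)
  h <- grDevices::chull(x, y)
  list(lon = x[h], lat = y[h])
}

# --- memoized pipeline run shared across test files -------------------------

.pipeline_cache <- new.env(parent = emptyenv())

cached_pipeline <- function(seed = 3L) {
  key <- paste0("run_", seed)
  if (is.null(.pipeline_cache[[key]])) {
    out_dir <- file.path(tempdir(), paste0("tl_pipe_", seed))
    .pipeline_cache[[key]] <- suppressMessages(suppressWarnings(
      run_pipeline(pipeline_config(out_dir = out_dir, seed = seed,
                                   agent = "test-runner"))))
  }
  .pipeline_cache[[key]]
}
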