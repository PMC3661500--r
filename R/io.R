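# Output writers (step log, vector layers), readers, and run summaries.

.fmt_num <- function(x) {
  # full-precision, locale-independent numeric formatting for GeoJSON
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE),
         character(1))
}

#' Write polygons with attributes to a GeoJSON file
#'
#' @param polys list of polygon matrices (rings, last vertex not repeated).
#' @param props data frame of feature properties (one row per polygon); may
#'   have zero rows for an empty layer.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_polygon_layer <- function(polys, props, path) {
  props <- as.data.frame(props)
  stopifnot(length(polys) == nrow(props))
  feats <- character(length(polys))
  for (i in seq_along(polys)) {
    ring <- polys[[i]]
    ring <- rbind(ring, ring[1, ])          # GeoJSON closes the ring
    coords <- paste0("[", .fmt_num(ring[, 1]), ",", .fmt_num(ring[, 2]), "]",
                     collapse = ",")
    pr <- jsonlite::toJSON(as.list(props[i, , drop = FALSE]),
                           auto_unbox = TRUE, digits = NA)
    feats[i] <- paste0(
      '{"type":"Feature","properties":', pr,
      ',"geometry":{"type":"Polygon","coordinates":[[', coords, ']]}}')
  }
  txt <- paste0('{"type":"FeatureCollection","features":[',
                paste(feats, collapse = ","), ']}')
  writeLines(txt, path)
  invisible(path)
}

#' Read a polygon layer written by [write_polygon_layer()]
#'
#' @param path GeoJSON file.
#' @return list with `polys` (list of matrices, ring unclosed) and `props`
#'   (data frame).
#' @export
read_polygon_layer <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- list()
  rows <- list()
  for (ft in gj$features) {
    ring <- do.call(rbind, lapply(ft$geometry$coordinates[[1]], function(c2) {
      c(as.numeric(c2[[1]]), as.numeric(c2[[2]]))
    }))
    n <- nrow(ring)
    if (n > 1 && all(abs(ring[1, ] - ring[n, ]) < 1e-12)) {
      ring <- ring[-n, , drop = FALSE]
    }
    polys[[length(polys) + 1L]] <- ring
    rows[[length(rows) + 1L]] <- as.data.frame(ft$properties)
  }
  props <- if (length(rows)) do.call(rbind, rows) else data.frame()
  list(polys = polys, props = props)
}

#' Write point features (e.g. a release layer) to GeoJSON
#'
#' @param pts data frame with `x`, `y` and any further property columns.
#' @param path output file.
#' @export
write_point_layer <- function(pts, path) {
  pts <- as.data.frame(pts)
  propcols <- setdiff(names(pts), c("x", "y"))
  feats <- character(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    pr <- jsonlite::toJSON(as.list(pts[i, propcols, drop = FALSE]),
                           auto_unbox = TRUE, digits = NA)
    feats[i] <- paste0(
      '{"type":"Feature","properties":', pr,
      ',"geometry":{"type":"Point","coordinates":[',
      .fmt_num(pts$x[i]), ",", .fmt_num(pts$y[i]), "]}}")
  }
  txt <- paste0('{"type":"FeatureCollection","features":[',
                paste(feats, collapse = ","), ']}')
  writeLines(txt, path)
  invisible(path)
}

#' Read a point layer (release points)
#'
#' @param path GeoJSON file of Point features.
#' @return data frame with `x`, `y` and the feature properties.
#' @export
read_point_layer <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(gj$features, function(ft) {
    cc <- ft$geometry$coordinates
    cbind(data.frame(x = as.numeric(cc[[1]]), y = as.numeric(cc[[2]])),
          as.data.frame(ft$properties))
  })
  do.call(rbind, rows)
}

#' Write the per-step log as delimited text
#'
#' One row per animal per time-step (year, day, step, id, sex, position,
#' energy, activity flags, status, cause of death, settled flag) with a
#' header row; plain CSV so determinism can be checked by diffing files.
#'
#' @param log the `log` element of a `dispersim_result` (or compatible
#'   data frame).
#' @param path output file.
#' @export
write_step_log <- function(log, path) {
  data.table::fwrite(as.data.frame(log), path)
  invisible(path)
}

#' Read a step log back
#' @param path CSV from [write_step_log()].
#' @return data frame.
#' @export
read_step_log <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write the seasonal vector outputs of a run
#'
#' Per year: a home-range polygon layer (owner id, sex, year, area) and,
#' when corridors were recorded, a perception-corridor layer (animal id).
#' Layers with no features are written as valid empty collections.
#'
#' @param result a `dispersim_result`.
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
write_vector_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  years <- seq_len(result$config$years)
  for (y in years) {
    rngs <- Filter(function(r) !is.null(r$year) && r$year == y, result$ranges)
    polys <- lapply(rngs, `[[`, "poly")
    props <- if (length(rngs)) {
      data.frame(owner = vapply(rngs, function(r) as.integer(r$owner), integer(1)),
                 sex = vapply(rngs, `[[`, character(1), "sex"),
                 year = y,
                 area = vapply(polys, geom_area, numeric(1)))
    } else {
      data.frame(owner = integer(0), sex = character(0), year = integer(0),
                 area = numeric(0))
    }
    p1 <- file.path(dir, sprintf("home_ranges_year%d.geojson", y))
    write_polygon_layer(polys, props, p1)
    written <- c(written, p1)

    keys <- grep(paste0("^", y, "_"), names(result$corridors), value = TRUE)
    cp <- list(); cid <- integer(0)
    for (k in keys) {
      id <- as.integer(sub("^\\d+_", "", k))
      for (piece in result$corridors[[k]]) {
        cp[[length(cp) + 1L]] <- piece
        cid <- c(cid, id)
      }
    }
    p2 <- file.path(dir, sprintf("perception_year%d.geojson", y))
    write_polygon_layer(cp, data.frame(animal = cid), p2)
    written <- c(written, p2)
  }
  invisible(written)
}

#' Summarise a completed run
#'
#' Per year and overall: number of dispersers; overall mortality rate and
#' its cause-specific components (predation, starvation, failure to settle
#' by season end — the components sum to the overall rate); number settled;
#' mean and sd of the energy (weight) change of settlers; mean settlement
#' time in steps; mean straight-line dispersal distance from natal origin
#' to range centre.
#'
#' @param result a `dispersim_result`.
#' @return data frame, one row per year plus an `"overall"` row.
#' @export
summarize_run <- function(result) {
  an <- result$animals
  if (is.null(an) || !nrow(an)) {
    return(data.frame(year = "overall", n = 0L, mortality = NA_real_,
                      mortality_predation = NA_real_,
                      mortality_starvation = NA_real_,
                      mortality_season_end = NA_real_, n_settled = 0L,
                      weight_change_mean = NA_real_, weight_change_sd = NA_real_,
                      settlement_steps_mean = NA_real_,
                      dispersal_distance_mean = NA_real_))
  }
  one <- function(d, label) {
    n <- nrow(d)
    dead <- d$status == "dead"
    settled <- d$status == "settled"
    wc <- d$energy_final[settled] - d$energy_init[settled]
    data.frame(
      year = label, n = n,
      mortality = mean(dead),
      mortality_predation = mean(d$cause == "predation"),
      mortality_starvation = mean(d$cause == "starvation"),
      mortality_season_end = mean(d$cause == "season_end"),
      n_settled = sum(settled),
      weight_change_mean = if (length(wc)) mean(wc) else NA_real_,
      weight_change_sd = if (length(wc) > 1) stats::sd(wc) else NA_real_,
      settlement_steps_mean = if (any(settled))
        mean(d$settled_step[settled]) else NA_real_,
      dispersal_distance_mean = if (any(settled))
        mean(d$dispersal_distance[settled]) else NA_real_
    )
  }
  out <- do.call(rbind, lapply(split(an, an$year), function(d)
    one(d, as.character(d$year[1]))))
  rbind(out, one(an, "overall"))
}
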