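# Parameter maps and the landscape container.
#
# A landscape is five layers: four polygon parameter maps (movement, food,
# risk, suitability) whose features carry the role-specific attributes below,
# plus a point release layer.  Any map can be replaced at a scheduled time
# (map swapping), which is how seasonal food pulses or day/night predation
# are represented.

.map_roles <- c("movement", "food", "risk", "suitability")

# required fields and legal ranges per role; range is c(lo, hi) with NA = open
.role_fields <- list(
  movement = list(
    tortuosity     = c(0, 1),
    step_mean      = c(0, NA),
    step_sd        = c(0, NA),
    energy_cost    = c(0, NA),
    crossing       = c(0, NA),
    perception_mod = c(0, NA)
  ),
  food = list(
    p_capture = c(0, 1),
    size_mean = c(0, NA),
    size_sd   = c(0, NA)
  ),
  risk = list(
    p_mortality = c(0, 1)
  ),
  suitability = list(
    suitable        = c(0, 1),
    occupied_male   = c(0, 1),
    occupied_female = c(0, 1)
  )
)

.stop_cfg <- function(...) {
  stop(errorCondition(paste0(...), class = c("dispersim_config_error", "error")))
}
.stop_val <- function(...) {
  stop(errorCondition(paste0(...), class = c("dispersim_validation_error", "error")))
}

#' Construct a parameter map from polygons and attributes
#'
#' A parameter map is a tessellation of its rectangular extent by simple
#' polygons, each carrying the attribute record its role requires (movement,
#' food, risk or suitability).  Validation enforces attribute ranges, binary
#' suitability/occupancy flags, and full coverage of the extent (a hole in
#' the tessellation is an error because every animal location must yield
#' attributes).
#'
#' @param role one of `"movement"`, `"food"`, `"risk"`, `"suitability"`.
#' @param polys list of two-column coordinate matrices (simple polygon rings,
#'   planar metres, last vertex not repeated).
#' @param attrs data frame with one row per polygon and the role's required
#'   columns (see Details).
#' @param validate check ranges and coverage (default `TRUE`).
#'
#' @details Required columns by role: movement needs `tortuosity` (wrapped
#'   Cauchy concentration in \[0,1\]), `step_mean`, `step_sd` (metres per
#'   time-step), `energy_cost` (energy units per time-step), `crossing`
#'   (permeability rank, 0 = impassable) and `perception_mod`; food needs
#'   `p_capture`, `size_mean`, `size_sd`; risk needs `p_mortality`;
#'   suitability needs binary `suitable`, `occupied_male`, `occupied_female`.
#'
#' @return an object of class `dispersim_map`.
#' @export
parameter_map <- function(role, polys, attrs, validate = TRUE) {
  role <- match.arg(role, .map_roles)
  if (!is.list(polys) || !length(polys)) .stop_cfg("empty polygon list")
  polys <- lapply(polys, function(p) geom_ccw(as.matrix(p)))
  attrs <- as.data.frame(attrs)
  if (nrow(attrs) != length(polys)) {
    .stop_cfg("attrs has ", nrow(attrs), " rows for ", length(polys), " polygons")
  }
  req <- .role_fields[[role]]
  for (f in names(req)) {
    if (is.null(attrs[[f]])) .stop_cfg("missing required field '", f,
                                       "' for role '", role, "'")
    v <- as.numeric(attrs[[f]])
    if (anyNA(v)) .stop_val("field '", f, "' contains non-numeric values")
    attrs[[f]] <- v
  }
  bboxes <- t(vapply(polys, geom_bbox, numeric(4)))
  extent <- c(min(bboxes[, 1]), min(bboxes[, 2]), max(bboxes[, 3]), max(bboxes[, 4]))
  m <- structure(
    list(role = role, polys = polys, attrs = attrs,
         ids = seq_along(polys), bboxes = bboxes, extent = extent),
    class = "dispersim_map"
  )
  if (validate) validate_map(m) else m
}

#' Validate a parameter map
#'
#' Checks attribute ranges per role, binary flags for suitability maps, and
#' that the features tessellate the extent (summed feature area equals the
#' extent area within 1e-6 relative tolerance).  Idempotent.
#'
#' @param map a `dispersim_map`.
#' @return the map, invisibly usable, unchanged.
#' @export
validate_map <- function(map) {
  stopifnot(inherits(map, "dispersim_map"))
  req <- .role_fields[[map$role]]
  binary <- map$role == "suitability"
  for (f in names(req)) {
    v <- map$attrs[[f]]
    rng <- req[[f]]
    bad <- (!is.na(rng[1]) & v < rng[1]) | (!is.na(rng[2]) & v > rng[2])
    if (any(bad)) {
      .stop_val("field '", f, "' out of range [", rng[1], ",",
                ifelse(is.na(rng[2]), "Inf", rng[2]), "] in feature ",
                which(bad)[1], " (value ", v[which(bad)[1]], ")")
    }
    if (binary && any(v != 0 & v != 1)) {
      .stop_val("field '", f, "' must be 0 or 1 in feature ",
                which(v != 0 & v != 1)[1])
    }
  }
  for (i in seq_along(map$polys)) {
    if (nrow(map$polys[[i]]) < 3) .stop_val("feature ", i, " is not a polygon")
  }
  areas <- vapply(map$polys, geom_area, numeric(1))
  ext_area <- (map$extent[3] - map$extent[1]) * (map$extent[4] - map$extent[2])
  if (ext_area > 0 && abs(sum(areas) - ext_area) > 1e-6 * ext_area) {
    .stop_val("features do not tessellate the extent: total feature area ",
              signif(sum(areas), 10), " vs extent area ", signif(ext_area, 10),
              " (gaps or overlaps)")
  }
  map
}

#' Read a polygon parameter map from a GeoJSON file
#'
#' Arbitrary property names in the file are bound to the role's required
#' fields through `field_map`, so users need not rename their GIS attributes.
#' Only `Polygon` geometries (outer ring, no holes) are accepted; coordinates
#' are taken as pre-projected planar metres.
#'
#' @param path GeoJSON file with a `FeatureCollection` of polygons.
#' @param role map role (movement, food, risk, suitability).
#' @param field_map named character vector or list mapping each required
#'   field name to the property name used in the file; defaults to the
#'   required names themselves.
#' @return a validated `dispersim_map`.
#' @export
load_parameter_map <- function(path, role, field_map = NULL) {
  role <- match.arg(role, .map_roles)
  if (!file.exists(path)) .stop_cfg("file not found: ", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) .stop_cfg("not a GeoJSON FeatureCollection: ", path)
  req <- names(.role_fields[[role]])
  fm <- as.list(field_map %||% stats::setNames(as.list(req), req))
  missing_fm <- setdiff(req, names(fm))
  if (length(missing_fm)) {
    .stop_cfg("field_map does not name required field(s): ",
              paste(missing_fm, collapse = ", "))
  }
  polys <- vector("list", length(gj$features))
  rows <- vector("list", length(gj$features))
  for (i in seq_along(gj$features)) {
    ft <- gj$features[[i]]
    geom <- ft$geometry
    if (is.null(geom) || !identical(geom$type, "Polygon")) {
      stop(errorCondition(
        paste0("feature ", i, ": geometry type '",
               geom$type %||% "NULL", "' is not Polygon"),
        class = c("dispersim_format_error", "error")))
    }
    if (length(geom$coordinates) > 1) {
      .stop_val("feature ", i, ": polygon has interior ring(s); ",
                "holes are not allowed in a tessellation")
    }
    ring <- do.call(rbind, lapply(geom$coordinates[[1]], function(c2) {
      c(as.numeric(c2[[1]]), as.numeric(c2[[2]]))
    }))
    # GeoJSON closes the ring; drop the repeated last vertex
    n <- nrow(ring)
    if (n > 1 && all(abs(ring[1, ] - ring[n, ]) < 1e-12)) {
      ring <- ring[-n, , drop = FALSE]
    }
    polys[[i]] <- ring
    props <- ft$properties
    vals <- lapply(req, function(f) {
      v <- props[[fm[[f]]]]
      if (is.null(v)) .stop_cfg("feature ", i, ": missing field '", fm[[f]],
                                "' (mapped to '", f, "')")
      as.numeric(v)
    })
    names(vals) <- req
    rows[[i]] <- as.data.frame(vals)
  }
  parameter_map(role, polys, do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate the feature containing a point
#'
#' Containment is boundary-inclusive; a point on a shared edge resolves to
#' the feature with the smallest id, so tessellation queries are
#' deterministic.
#' @param strict prefer the tolerance-free even-odd test (used by the
#'   movement traversal so that a point a hair past a shared edge anchors
#'   to the side the ray travels through); falls back to the
#'   edge-inclusive min-id rule for points exactly on an edge.
#' @noRd
locate_feature <- function(map, p, strict = FALSE) {
  b <- map$bboxes
  eps <- 1e-9 * max(map$extent[3] - map$extent[1], map$extent[4] - map$extent[2], 1)
  cand <- which(p[1] >= b[, 1] - eps & p[1] <= b[, 3] + eps &
                p[2] >= b[, 2] - eps & p[2] <= b[, 4] + eps)
  if (strict) {
    for (i in cand) {
      if (point_in_poly(p[1], p[2], map$polys[[i]], boundary = FALSE)) return(i)
    }
  }
  for (i in cand) {   # ids are ordered, first hit = smallest id
    if (point_in_poly(p[1], p[2], map$polys[[i]])) return(i)
  }
  NA_integer_
}

#' Query the attributes at a point
#'
#' Returns the attribute record of the unique polygon containing `p`; on a
#' shared edge the smallest feature id wins.
#'
#' @param map a `dispersim_map`.
#' @param p numeric length-2 point (x, y) in map units.
#' @return one-row data frame of the role's attributes, with a `feature_id`
#'   column appended.
#' @export
attrs_at <- function(map, p) {
  i <- locate_feature(map, p)
  if (is.na(i)) {
    stop(errorCondition(
      paste0("point (", p[1], ", ", p[2], ") is outside the map extent"),
      class = c("dispersim_bounds_error", "error")))
  }
  out <- map$attrs[i, , drop = FALSE]
  out$feature_id <- map$ids[i]
  out
}

#' Suitable and occupied area of a region on a suitability map
#'
#' Intersects a query region with a suitability map and returns the area
#' that is suitable, occupied by a male, and occupied by a female.  Used to
#' decide settlement and to audit same-sex exclusion.
#'
#' @param map a suitability `dispersim_map`.
#' @param region a polygon matrix, or a list of polygons (treated as a union
#'   of non-overlapping pieces).
#' @return named numeric: `suitable`, `occupied_male`, `occupied_female`
#'   areas in square map units.
#' @export
region_status <- function(map, region) {
  if (!identical(map$role, "suitability")) {
    .stop_cfg("region_status requires a suitability map")
  }
  out <- c(suitable = 0, occupied_male = 0, occupied_female = 0)
  if (is.null(region) || (is.list(region) && !length(region))) return(out)
  pieces <- region_pieces(region)
  if (!length(pieces)) return(out)
  rb <- sapply(pieces, geom_bbox)
  rbb <- c(min(rb[1, ]), min(rb[2, ]), max(rb[3, ]), max(rb[4, ]))
  b <- map$bboxes
  cand <- which(b[, 1] <= rbb[3] & b[, 3] >= rbb[1] &
                b[, 2] <= rbb[4] & b[, 4] >= rbb[2])
  for (i in cand) {
    a <- 0
    for (pc in pieces) a <- a + intersection_area(map$polys[[i]], pc)
    if (a <= 0) next
    at <- map$attrs[i, ]
    if (at$suitable == 1) out["suitable"] <- out["suitable"] + a
    if (at$occupied_male == 1) out["occupied_male"] <- out["occupied_male"] + a
    if (at$occupied_female == 1) out["occupied_female"] <- out["occupied_female"] + a
  }
  out
}

#' Absolute simulation time in minutes
#'
#' The simulation clock counts minutes from midnight of day 1 of year 1 of
#' the dispersal season; years are concatenated season blocks (the
#' inter-dispersal period is a single discrete event between them and
#' occupies no clock time).
#'
#' @param year,day,hour calendar position within the simulation (1-based
#'   year and day-of-season; hour may be fractional).
#' @param season_days days in each dispersal season.
#' @return minutes since the simulation origin.
#' @export
sim_minutes <- function(year, day, hour, season_days) {
  ((year - 1) * season_days + (day - 1)) * 1440 + hour * 60
}

#' Create a map-swap event
#'
#' @param year,day,hour when the replacement takes effect (the first
#'   time-step whose timestamp is at or after this moment uses the new map).
#' @param role which layer is replaced.
#' @param map the replacement `dispersim_map` (validated like the original).
#' @param season_days season length used to place the event on the clock.
#' @return a `dispersim_swap` event.
#' @export
swap_event <- function(year, day, hour, role, map, season_days) {
  role <- match.arg(role, .map_roles)
  stopifnot(inherits(map, "dispersim_map"), identical(map$role, role))
  validate_map(map)
  structure(list(at = sim_minutes(year, day, hour, season_days),
                 year = year, day = day, hour = hour,
                 role = role, map = map),
            class = "dispersim_swap")
}

#' Expand a daily two-phase swap into per-day events
#'
#' Convenience for diurnal schedules such as day/night predation risk: the
#' `day_map` takes effect at `day_start` and the `night_map` at
#' `night_start` on every day of every season.
#'
#' @param day_map,night_map replacement maps of the same role.
#' @param day_start,night_start hours of day (defaults 6 and 18).
#' @param years,season_days simulation horizon.
#' @return list of `dispersim_swap` events in time order.
#' @export
daily_swap_schedule <- function(day_map, night_map, day_start = 6,
                                night_start = 18, years, season_days) {
  role <- day_map$role
  ev <- list()
  for (y in seq_len(years)) {
    for (d in seq_len(season_days)) {
      ev[[length(ev) + 1L]] <- swap_event(y, d, day_start, role, day_map, season_days)
      ev[[length(ev) + 1L]] <- swap_event(y, d, night_start, role, night_map, season_days)
    }
  }
  ev
}

#' Assemble a landscape
#'
#' @param movement,food,risk,suitability the four validated parameter maps.
#'   All must share one coordinate frame; their extents must agree within
#'   tolerance.
#' @param release data frame of release points with columns `x`, `y`,
#'   `count` (integer >= 1) and optionally `sex` (`"male"`/`"female"`);
#'   may be `NULL` for resident-only scenarios.
#' @param swaps list of `dispersim_swap` events; per role, event times must
#'   be strictly increasing.
#' @return an object of class `dispersim_landscape`.
#' @export
landscape <- function(movement, food, risk, suitability, release = NULL,
                      swaps = list()) {
  maps <- list(movement = movement, food = food, risk = risk,
               suitability = suitability)
  for (r in .map_roles) {
    m <- maps[[r]]
    if (!inherits(m, "dispersim_map") || !identical(m$role, r)) {
      .stop_cfg("'", r, "' must be a dispersim_map with role '", r, "'")
    }
  }
  ext <- movement$extent
  tol <- 1e-6 * max(ext[3] - ext[1], ext[4] - ext[2])
  for (r in .map_roles[-1]) {
    if (any(abs(maps[[r]]$extent - ext) > tol)) {
      .stop_cfg("map extents differ between movement and ", r)
    }
  }
  if (!is.null(release)) {
    release <- as.data.frame(release)
    if (is.null(release$x) || is.null(release$y)) {
      .stop_cfg("release layer needs x and y columns")
    }
    if (is.null(release$count)) release$count <- 1L
    if (any(release$count < 1)) .stop_cfg("release count must be >= 1")
  }
  for (s in swaps) {
    if (!inherits(s, "dispersim_swap")) .stop_cfg("swaps must be dispersim_swap events")
  }
  if (length(swaps)) {
    byrole <- split(vapply(swaps, `[[`, numeric(1), "at"),
                    vapply(swaps, `[[`, character(1), "role"))
    for (r in names(byrole)) {
      if (any(diff(sort(byrole[[r]])) <= 0) ||
          is.unsorted(byrole[[r]], strictly = TRUE)) {
        .stop_cfg("swap events for role '", r, "' are not strictly ordered in time")
      }
    }
  }
  structure(list(maps = maps, release = release, swaps = swaps, extent = ext),
            class = "dispersim_landscape")
}

#' The map active at a simulation time
#'
#' Returns the initial map if no swap event for the role has occurred at or
#' before `t_min`, otherwise the replacement carried by the latest such
#' event.  Piecewise constant and right-continuous in time: an event applies
#' at exactly its timestamp.
#'
#' @param land a `dispersim_landscape`.
#' @param role map role.
#' @param t_min absolute simulation time in minutes (see [sim_minutes()]).
#' @return a `dispersim_map`.
#' @export
active_map <- function(land, role, t_min) {
  role <- match.arg(role, .map_roles)
  best <- NULL; best_at <- -Inf
  for (s in land$swaps) {
    if (identical(s$role, role) && s$at <= t_min && s$at > best_at) {
      best <- s$map; best_at <- s$at
    }
  }
  best %||% land$maps[[role]]
}

#' @export
print.dispersim_map <- function(x, ...) {
  cat("<dispersim_map> role:", x$role, "|", length(x$polys), "features | extent [",
      paste(signif(x$extent, 6), collapse = ", "), "]\n")
  invisible(x)
}

#' @export
print.dispersim_landscape <- function(x, ...) {
  cat("<dispersim_landscape> extent [", paste(signif(x$extent, 6), collapse = ", "),
      "] |", length(x$swaps), "swap event(s) |",
      if (is.null(x$release)) 0L else nrow(x$release), "release point(s)\n")
  invisible(x)
}
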