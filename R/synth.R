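# Synthetic-landscape generator.  Produces tessellated polygon parameter
# maps with per-class attributes, standing in for digitised GIS landscapes
# (which are typically not distributable) in tests, examples and acceptance
# runs.  Supports paired map variants for swap schedules, e.g. a scarce vs
# superabundant food phase or day vs night predation risk.

#' Default two-class attribute table
#'
#' A simple matrix/field habitat: "habitat" is passable, suitable, safe-ish
#' and food-rich; "matrix" is less permeable, unsuitable and riskier.
#' @return data frame usable as the `classes` argument of
#'   [synthetic_landscape()].
#' @export
default_classes <- function() {
  data.frame(
    name = c("habitat", "matrix"),
    weight = c(0.6, 0.4),
    tortuosity = c(0.6, 0.8),
    step_mean = c(100, 150),
    step_sd = c(10, 15),
    energy_cost = c(1, 2),
    crossing = c(3, 1),
    perception_mod = c(1, 1),
    p_capture = c(0.3, 0.05),
    size_mean = c(5, 2),
    size_sd = c(1, 0.5),
    p_mortality = c(1e-4, 5e-4),
    suitable = c(1, 0)
  )
}

.class_cols <- list(
  movement = c("tortuosity", "step_mean", "step_sd", "energy_cost",
               "crossing", "perception_mod"),
  food = c("p_capture", "size_mean", "size_sd"),
  risk = c("p_mortality"),
  suitability = c("suitable")
)

.maps_from_classes <- function(polys, assignment, classes) {
  maps <- list()
  for (role in .map_roles) {
    at <- classes[assignment, .class_cols[[role]], drop = FALSE]
    if (role == "suitability") {
      at$occupied_male <- 0
      at$occupied_female <- 0
    }
    rownames(at) <- NULL
    at$class <- classes$name[assignment]
    maps[[role]] <- parameter_map(role, polys, at)
  }
  maps
}

#' Generate a synthetic landscape
#'
#' Tessellates a rectangular extent into patches (a regular grid, exact
#' areas; or a Voronoi tessellation of random sites, irregular convex
#' patches), assigns each patch a habitat class by a seeded draw weighted
#' by the class table, and builds the four parameter maps from the class
#' attributes.  All four maps share the tessellation.
#'
#' @param extent c(xmin, ymin, xmax, ymax) in metres.
#' @param tessellation `"grid"` or `"voronoi"`.
#' @param nx,ny grid dimensions (grid mode).
#' @param n_patches number of Voronoi sites (voronoi mode).
#' @param classes class attribute table (see [default_classes()]): columns
#'   `name`, `weight` and the per-role attribute columns.
#' @param release optional release-point data frame (`x`, `y`, `count`,
#'   optionally `sex`).
#' @param swaps optional list of `dispersim_swap` events.
#' @param seed optional integer; when given, `set.seed` is called so the
#'   same spec and seed always produce the identical landscape.
#' @return a list of class `dispersim_synth`: `landscape`
#'   (a `dispersim_landscape`), `polys`, `assignment` (class index per
#'   patch), `classes`.
#' @export
synthetic_landscape <- function(extent = c(0, 0, 1000, 1000),
                                tessellation = c("grid", "voronoi"),
                                nx = 10, ny = 10, n_patches = 50,
                                classes = default_classes(),
                                release = NULL, swaps = list(), seed = NULL) {
  tessellation <- match.arg(tessellation)
  classes <- as.data.frame(classes)
  stopifnot(!is.null(classes$name), !is.null(classes$weight))
  if (!is.null(seed)) set.seed(seed)
  if (tessellation == "grid") {
    xs <- seq(extent[1], extent[3], length.out = nx + 1)
    ys <- seq(extent[2], extent[4], length.out = ny + 1)
    polys <- list()
    for (j in seq_len(ny)) {
      for (i in seq_len(nx)) {
        polys[[length(polys) + 1L]] <- cbind(
          c(xs[i], xs[i + 1], xs[i + 1], xs[i]),
          c(ys[j], ys[j], ys[j + 1], ys[j + 1]))
      }
    }
  } else {
    sites <- cbind(stats::runif(n_patches, extent[1], extent[3]),
                   stats::runif(n_patches, extent[2], extent[4]))
    polys <- voronoi_cells(sites, extent)
  }
  assignment <- sample.int(nrow(classes), length(polys), replace = TRUE,
                           prob = classes$weight)
  maps <- .maps_from_classes(polys, assignment, classes)
  land <- landscape(maps$movement, maps$food, maps$risk, maps$suitability,
                    release = release, swaps = swaps)
  structure(list(landscape = land, polys = polys, assignment = assignment,
                 classes = classes), class = "dispersim_synth")
}

#' Build a variant parameter map from modified class attributes
#'
#' Reuses a synthetic landscape's tessellation and class assignment but
#' substitutes different attribute values for (some) classes — the standard
#' way to construct the second phase of a swap schedule, e.g. a
#' superabundant-food version of the food map or a nighttime risk map.
#'
#' @param synth a `dispersim_synth`.
#' @param role which map to rebuild.
#' @param overrides data frame with a `name` column naming classes and any
#'   attribute columns to replace.
#' @return a `dispersim_map` of the requested role.
#' @export
map_variant <- function(synth, role, overrides) {
  role <- match.arg(role, .map_roles)
  classes <- synth$classes
  overrides <- as.data.frame(overrides)
  stopifnot(!is.null(overrides$name))
  for (i in seq_len(nrow(overrides))) {
    j <- match(overrides$name[i], classes$name)
    if (is.na(j)) .stop_cfg("unknown class '", overrides$name[i], "'")
    for (col in setdiff(names(overrides), "name")) {
      classes[[col]][j] <- overrides[[col]][i]
    }
  }
  .maps_from_classes(synth$polys, synth$assignment, classes)[[role]]
}

#' Generate and write a synthetic landscape file set
#'
#' Writes the four polygon parameter maps and the release point layer as
#' GeoJSON under `dir`.  The same spec and seed always produce
#' byte-identical files.
#'
#' @inheritParams synthetic_landscape
#' @param dir output directory (created if absent).
#' @param seed integer seed (required here: files must be reproducible).
#' @return named character vector of the written paths.
#' @export
generate_synthetic_landscape <- function(dir, extent = c(0, 0, 1000, 1000),
                                         tessellation = "grid",
                                         nx = 10, ny = 10, n_patches = 50,
                                         classes = default_classes(),
                                         release = NULL, seed = 1L) {
  syn <- synthetic_landscape(extent = extent, tessellation = tessellation,
                             nx = nx, ny = ny, n_patches = n_patches,
                             classes = classes, release = release, seed = seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (role in .map_roles) {
    m <- syn$landscape$maps[[role]]
    p <- file.path(dir, paste0(role, ".geojson"))
    write_polygon_layer(m$polys, m$attrs, p)
    paths[role] <- p
  }
  if (!is.null(release)) {
    p <- file.path(dir, "release.geojson")
    write_point_layer(release, p)
    paths["release"] <- p
  }
  paths
}
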