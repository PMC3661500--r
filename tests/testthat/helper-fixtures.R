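# Fixture builders shared across the test files.  Everything is constructed
# in code; no binary fixtures.

# rectangle ring (unclosed)
rect_poly <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

# two side-by-side unit-km cells with per-role attributes
two_cell_map <- function(role, attrs) {
  polys <- list(rect_poly(0, 0, 500, 1000), rect_poly(500, 0, 1000, 1000))
  parameter_map(role, polys, attrs)
}

# 2x2 movement map with four crossing ranks (row-major from bottom-left)
quad_movement_map <- function(crossing = c(1, 2, 3, 4), step_mean = 150,
                              step_sd = 15, tortuosity = 0.3) {
  polys <- list(rect_poly(0, 0, 500, 500), rect_poly(500, 0, 1000, 500),
                rect_poly(0, 500, 500, 1000), rect_poly(500, 500, 1000, 1000))
  parameter_map("movement", polys, data.frame(
    tortuosity = tortuosity, step_mean = step_mean, step_sd = step_sd,
    energy_cost = 1, crossing = crossing, perception_mod = 1))
}

# single-polygon homogeneous maps over a square extent
homog_maps <- function(L = 1000, tortuosity = 0.5, step_mean = 100,
                       step_sd = 0, energy_cost = 1, crossing = 1,
                       p_capture = 0, size_mean = 0, size_sd = 0,
                       p_mortality = 0, suitable = 1) {
  poly <- list(rect_poly(0, 0, L, L))
  list(
    movement = parameter_map("movement", poly, data.frame(
      tortuosity = tortuosity, step_mean = step_mean, step_sd = step_sd,
      energy_cost = energy_cost, crossing = crossing, perception_mod = 1)),
    food = parameter_map("food", poly, data.frame(
      p_capture = p_capture, size_mean = size_mean, size_sd = size_sd)),
    risk = parameter_map("risk", poly, data.frame(p_mortality = p_mortality)),
    suitability = parameter_map("suitability", poly, data.frame(
      suitable = suitable, occupied_male = 0, occupied_female = 0))
  )
}

homog_landscape <- function(L = 1000, release = NULL, swaps = list(), ...) {
  m <- homog_maps(L = L, ...)
  landscape(m$movement, m$food, m$risk, m$suitability,
            release = release, swaps = swaps)
}

# effective parameters assembled directly (bypassing modifier resolution)
make_eff <- function(p_capture = 0, p_mortality = 0, energy_cost = 1,
                     step_mean = 100, step_sd = 0, tortuosity = 0.5,
                     crossing = 1, perception_radius = 0) {
  structure(list(p_capture = p_capture, p_mortality = p_mortality,
                 energy_cost = energy_cost, step_mean = step_mean,
                 step_sd = step_sd, tortuosity = tortuosity,
                 crossing = crossing, perception_radius = perception_radius),
            class = "dispersim_effective")
}

# brute-force point-in-feature oracle: scan every feature, boundary
# inclusive, smallest id wins
oracle_locate <- function(map, p) {
  for (i in seq_along(map$polys)) {
    if (dispersim:::point_in_poly(p[1], p[2], map$polys[[i]])) return(i)
  }
  NA_integer_
}

# write a small movement GeoJSON fixture by hand (text, not via the writer)
write_fixture_geojson <- function(path) {
  txt <- paste0(
    '{"type":"FeatureCollection","features":[',
    '{"type":"Feature","properties":{"tort":0.5,"sl":100,"sd":10,"ec":1,',
    '"cr":2,"pm":1},"geometry":{"type":"Polygon","coordinates":',
    '[[[0,0],[500,0],[500,1000],[0,1000],[0,0]]]}},',
    '{"type":"Feature","properties":{"tort":1.0,"sl":50,"sd":0,"ec":2,',
    '"cr":1,"pm":1},"geometry":{"type":"Polygon","coordinates":',
    '[[[500,0],[1000,0],[1000,1000],[500,1000],[500,0]]]}}]}')
  writeLines(txt, path)
  path
}

fixture_field_map <- c(tortuosity = "tort", step_mean = "sl", step_sd = "sd",
                       energy_cost = "ec", crossing = "cr",
                       perception_mod = "pm")
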