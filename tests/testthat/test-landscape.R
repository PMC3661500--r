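# Parameter-map loading, validation, point queries, region areas and map
# swapping.

test_that("a hand-written GeoJSON movement map round-trips with field mapping", {
  path <- withr::local_tempfile(fileext = ".geojson")
  write_fixture_geojson(path)
  m <- load_parameter_map(path, "movement", fixture_field_map)
  expect_s3_class(m, "dispersim_map")
  expect_identical(m$role, "movement")
  expect_length(m$polys, 2L)
  expect_equal(m$attrs$tortuosity, c(0.5, 1.0))
  expect_equal(m$attrs$step_mean, c(100, 50))
  expect_equal(m$extent, c(0, 0, 1000, 1000))
})

test_that("attribute range violations are rejected with the offending feature", {
  polys <- list(rect_poly(0, 0, 500, 1000), rect_poly(500, 0, 1000, 1000))
  base <- data.frame(tortuosity = c(0.5, 1), step_mean = 100, step_sd = 0,
                     energy_cost = 1, crossing = 1, perception_mod = 1)
  bad <- base; bad$tortuosity <- c(0.5, 1.3)
  expect_error(parameter_map("movement", polys, bad),
               class = "dispersim_validation_error")
  expect_error(parameter_map("movement", polys, bad), "tortuosity")

  suit <- data.frame(suitable = c(1, 2), occupied_male = 0, occupied_female = 0)
  expect_error(parameter_map("suitability", polys, suit),
               class = "dispersim_validation_error")

  nofield <- base; nofield$crossing <- NULL
  expect_error(parameter_map("movement", polys, nofield),
               class = "dispersim_config_error")
  expect_error(parameter_map("movement", polys, nofield), "crossing")
})

test_that("non-polygon geometry and tessellation gaps are rejected", {
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines(paste0(
    '{"type":"FeatureCollection","features":[{"type":"Feature",',
    '"properties":{"p_mortality":0.1},"geometry":{"type":"Point",',
    '"coordinates":[1,2]}}]}'), path)
  expect_error(load_parameter_map(path, "risk"),
               class = "dispersim_format_error")

  # a hole in the coverage: two polygons that do not fill their joint bbox
  polys <- list(rect_poly(0, 0, 400, 1000), rect_poly(500, 0, 1000, 1000))
  expect_error(parameter_map("risk", polys, data.frame(p_mortality = c(0, 0))),
               class = "dispersim_validation_error")
})

test_that("map validation is idempotent", {
  m <- quad_movement_map()
  expect_silent(validate_map(validate_map(m)))
})

test_that("attrs_at returns the containing polygon's record, min id on edges", {
  m <- two_cell_map("risk", data.frame(p_mortality = c(0.1, 0.2)))
  expect_equal(attrs_at(m, c(100, 100))$p_mortality, 0.1)
  expect_equal(attrs_at(m, c(900, 100))$p_mortality, 0.2)
  # point on the shared edge x = 500: smallest feature id wins
  expect_equal(attrs_at(m, c(500, 321))$feature_id, 1L)
  expect_error(attrs_at(m, c(2000, 2000)), class = "dispersim_bounds_error")
})

test_that("attrs_at agrees with a brute-force containment scan on random points", {
  m <- quad_movement_map()
  set.seed(11)
  for (k in 1:1000) {
    p <- c(runif(1, 0, 1000), runif(1, 0, 1000))
    expect_identical(attrs_at(m, p)$feature_id, oracle_locate(m, p))
  }
})

test_that("region_status computes suitable and occupied areas analytically", {
  m <- two_cell_map("suitability",
                    data.frame(suitable = c(1, 0),
                               occupied_male = c(0, 0), occupied_female = c(0, 0)))
  # region entirely inside the suitable cell
  r1 <- rect_poly(100, 100, 300, 300)
  st <- region_status(m, r1)
  expect_equal(unname(st["suitable"]), 200 * 200)
  expect_equal(unname(st["occupied_male"]), 0)
  # region straddling the boundary: half its area is suitable
  r2 <- rect_poly(400, 400, 600, 600)
  st2 <- region_status(m, r2)
  expect_equal(unname(st2["suitable"]), 200 * 200 / 2, tolerance = 1e-6)
  # empty region
  expect_equal(unname(region_status(m, list())), c(0, 0, 0))
  # occupancy flags are picked up
  m2 <- two_cell_map("suitability",
                     data.frame(suitable = c(1, 1),
                                occupied_male = c(0, 1), occupied_female = c(0, 0)))
  st3 <- region_status(m2, r2)
  expect_equal(unname(st3["occupied_male"]), 200 * 200 / 2, tolerance = 1e-6)
})

test_that("active_map follows the swap schedule and is right-continuous", {
  mk_food <- function(p) {
    parameter_map("food", list(rect_poly(0, 0, 1000, 1000)),
                  data.frame(p_capture = p, size_mean = 10, size_sd = 0))
  }
  scarce <- mk_food(0.1); rich <- mk_food(0.8)
  m <- homog_maps()
  sd150 <- 150
  swaps <- list(swap_event(1, 38, 0, "food", rich, sd150),
                swap_event(1, 114, 0, "food", scarce, sd150))
  land <- landscape(m$movement, scarce, m$risk, m$suitability, swaps = swaps)

  # no events for other roles: initial map at any t
  expect_identical(active_map(land, "risk", sim_minutes(1, 99, 12, sd150)),
                   m$risk)
  # before the first swap
  expect_equal(attrs_at(active_map(land, "food", sim_minutes(1, 10, 0, sd150)),
                        c(5, 5))$p_capture, 0.1)
  # day 50 falls in the superabundant phase (days 38-113)
  expect_equal(attrs_at(active_map(land, "food", sim_minutes(1, 50, 0, sd150)),
                        c(5, 5))$p_capture, 0.8)
  # right-continuity: the event applies at exactly its timestamp
  expect_equal(attrs_at(active_map(land, "food", sim_minutes(1, 38, 0, sd150)),
                        c(5, 5))$p_capture, 0.8)
  expect_equal(attrs_at(active_map(land, "food",
                                   sim_minutes(1, 38, 0, sd150) - 1),
                        c(5, 5))$p_capture, 0.1)
  # back to scarce from day 114
  expect_equal(attrs_at(active_map(land, "food", sim_minutes(1, 130, 0, sd150)),
                        c(5, 5))$p_capture, 0.1)
})

test_that("a daily day/night risk schedule swaps at 06:00 and 18:00", {
  mk_risk <- function(p) {
    parameter_map("risk", list(rect_poly(0, 0, 1000, 1000)),
                  data.frame(p_mortality = p))
  }
  day <- mk_risk(0.001); night <- mk_risk(0.01)
  m <- homog_maps()
  swaps <- daily_swap_schedule(day, night, 6, 18, years = 1, season_days = 30)
  land <- landscape(m$movement, m$food, night, m$suitability, swaps = swaps)
  p_at <- function(d, h) {
    attrs_at(active_map(land, "risk", sim_minutes(1, d, h, 30)), c(5, 5))$p_mortality
  }
  expect_equal(p_at(3, 19), 0.01)   # day 3, 19:00 -> night map
  expect_equal(p_at(3, 12), 0.001)  # noon -> day map
  expect_equal(p_at(3, 5), 0.01)    # pre-dawn -> previous night's map
  expect_equal(p_at(1, 6), 0.001)   # first swap applies at its timestamp
})

test_that("unordered swap events are rejected at landscape assembly", {
  mk_food <- function(p) {
    parameter_map("food", list(rect_poly(0, 0, 1000, 1000)),
                  data.frame(p_capture = p, size_mean = 10, size_sd = 0))
  }
  m <- homog_maps()
  swaps <- list(swap_event(1, 20, 0, "food", mk_food(0.5), 30),
                swap_event(1, 10, 0, "food", mk_food(0.6), 30))
  expect_error(landscape(m$movement, m$food, m$risk, m$suitability,
                         swaps = swaps),
               class = "dispersim_config_error")
})
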