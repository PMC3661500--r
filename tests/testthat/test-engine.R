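# Animal ordering, the per-step pipeline, the season/year loop and
# determinism.

small_run_cfg <- function(...) {
  defaults <- list(years = 1, season_days = 4, step_minutes = 60,
                   start_hour = 0, scenario = "release_only",
                   energy_init = 100, energy_min = 0, energy_max = 200,
                   perception_window = 100, trigger_mode = "steps",
                   trigger_threshold = 30, hr_criterion = "closest",
                   hr_w = 1e9, hr_min_area = list(male = 1e4, female = 1e4),
                   seed = 71)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_release <- data.frame(x = c(400, 600), y = c(400, 600), count = 1)

test_that("animals are ordered north to south, west to east, input-order free", {
  mk <- function(id, x, y) new_disperser(id, "male", c(x, y), 100, 0, 200)
  a <- mk(1, 0, 100); b <- mk(2, 0, 0); c <- mk(3, 50, 100)
  out <- order_animals(list(b, c, a))
  locs <- t(vapply(out, `[[`, numeric(2), "loc"))
  expect_equal(locs, rbind(c(0, 100), c(50, 100), c(0, 0)))  # N first, W ties
  expect_equal(vapply(out, `[[`, integer(1), "id"), 1:3)
  # permuting the input leaves the processing order unchanged
  out2 <- order_animals(list(c, a, b))
  locs2 <- t(vapply(out2, `[[`, numeric(2), "loc"))
  expect_equal(locs2, locs)
})

test_that("the season comprises season_days * 1440 / step_minutes steps", {
  land <- homog_landscape(L = 5000, release = data.frame(x = 2500, y = 2500,
                                                         count = 1))
  # raccoon frame: 150-day season at 1-h steps = 3600 steps
  cfg <- sim_config(years = 1, season_days = 150, step_minutes = 60,
                    scenario = "release_only", trigger_threshold = 1e6,
                    perception_window = 0, energy_init = 1e5, energy_min = 0,
                    energy_max = 2e5, hr_min_area = list(male = 1, female = 1),
                    record_corridors = FALSE, seed = 1)
  res <- run_simulation(cfg, land)
  expect_equal(res$n_steps_season, 3600L)
  expect_equal(nrow(res$log), 3600L)
  # chipmunk frame: 30-day season at 5-min steps = 8640 steps (computed
  # without running it)
  expect_equal(as.integer(floor(30 * 1440 / 5)), 8640L)
})

test_that("log timestamps are consistent with the simulation clock", {
  land <- homog_landscape(L = 2000, release = small_release)
  res <- run_simulation(small_run_cfg(), land)
  lg <- res$log
  # step k happens at start_hour*60 + (k-1)*step_minutes; day derived from it
  expect_true(all(lg$day == pmin((lg$step - 1L) %/% 24L + 1L, 4L)))
  expect_true(all(lg$step >= 1 & lg$step <= res$n_steps_season))
})

test_that("resting animals log a row but change nothing", {
  land <- homog_landscape(L = 2000, release = small_release,
                          energy_cost = 5, step_mean = 100)
  # active 1 h then 23 h rest from 00:00
  cfg <- small_run_cfg(active_mean = 1, rest_mean = 23,
                       trigger_threshold = 1e6)
  res <- run_simulation(cfg, land)
  lg <- res$log
  a1 <- lg[lg$id == 1, ]
  expect_true(all(!a1$active[2:24]))   # hours 2..24 of day 1 are rest
  # position and energy frozen during rest
  expect_equal(length(unique(a1$x[1:24])), 1L)
  expect_equal(length(unique(a1$energy[1:24])), 1L)
  # active again at the start of day 2
  expect_true(a1$active[25])
})

test_that("every dead animal carries exactly one cause of death", {
  land <- homog_landscape(L = 2000, release = small_release,
                          p_mortality = 0.02, energy_cost = 3)
  cfg <- small_run_cfg(trigger_threshold = 1e6)   # nobody settles
  res <- run_simulation(cfg, land)
  an <- res$animals
  expect_true(all(an$status %in% c("dead", "settled")))
  dead <- an[an$status == "dead", ]
  expect_true(all(dead$cause %in% c("predation", "starvation", "season_end")))
  expect_true(all(nchar(an$cause[an$status == "settled"]) == 0))
  # no log rows after an animal's death step
  for (id in unique(res$log$id)) {
    rows <- res$log[res$log$id == id, ]
    d <- which(rows$status == "dead")
    if (length(d)) expect_equal(d, nrow(rows))
  }
})

test_that("population accounting closes every season", {
  set.seed(1)
  syn <- synthetic_landscape(extent = c(0, 0, 3000, 3000), nx = 6, ny = 6,
                             release = data.frame(x = runif(6, 500, 2500),
                                                  y = runif(6, 500, 2500),
                                                  count = 1),
                             seed = 13)
  cfg <- small_run_cfg(trigger_threshold = 10)
  res <- run_simulation(cfg, syn$landscape)
  an <- res$animals
  expect_equal(nrow(an), 6L)
  expect_equal(sum(an$status == "settled") + sum(an$status == "dead"), 6L)
})

test_that("an extinct population still yields valid empty output", {
  land <- homog_landscape(L = 2000, release = small_release)
  # everyone dies at season end (no settlement possible), no breeding
  cfg <- sim_config(years = 3, season_days = 2, step_minutes = 60,
                    scenario = "release_only", trigger_threshold = 1e6,
                    hr_min_area = list(male = 1e4, female = 1e4),
                    p_pregnant = 0, seed = 5)
  res <- run_simulation(cfg, land)
  expect_equal(nrow(res$animals), 2L)         # only year 1 had animals
  expect_length(res$ranges, 0L)
  s <- summarize_run(res)
  expect_equal(s$mortality[s$year == "overall"], 1)
})

test_that("identical configuration and seed reproduce the log exactly", {
  land <- homog_landscape(L = 2000, release = small_release,
                          p_capture = 0.3, size_mean = 5, size_sd = 1,
                          p_mortality = 1e-4)
  cfg <- small_run_cfg(p_risky_to_safe = 0.01, p_safe_to_risky = 0.01)
  r1 <- run_simulation(cfg, land)
  r2 <- run_simulation(cfg, land)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$animals, r2$animals)
})

test_that("multi-year runs breed next-season dispersers from settlers", {
  set.seed(2)
  land <- homog_landscape(L = 6000, release = data.frame(
    x = c(1500, 4500), y = c(1500, 4500), count = 1))
  cfg <- sim_config(years = 2, season_days = 3, step_minutes = 60,
                    scenario = "release_only",
                    trigger_mode = "steps", trigger_threshold = 5,
                    hr_criterion = "closest", hr_w = 1e9,
                    hr_min_area = list(male = 1e4, female = 1e4),
                    perception_window = 150,
                    p_inter = 0, p_pregnant = 1, litter_mean = 2,
                    litter_sd = 0, p_female = 0.5, seed = 9)
  res <- run_simulation(cfg, land)
  an <- res$animals
  y1_settled <- sum(an$status == "settled" & an$year == 1)
  if (y1_settled > 0) {
    y2 <- an[an$year == 2, ]
    # one released female at most; offspring = 2 per surviving female
    expect_equal(nrow(y2),
                 2 * sum(an$year == 1 & an$status == "settled" &
                         an$sex == "female"))
    if (nrow(y2)) {
      # offspring natal origins coincide with some settled range centre
      y1s <- an[an$year == 1 & an$status == "settled", ]
      for (i in seq_len(nrow(y2))) {
        expect_true(any(abs(y1s$range_x - y2$natal_x[i]) < 1e-9 &
                        abs(y1s$range_y - y2$natal_y[i]) < 1e-9))
      }
    }
  } else {
    succeed("no settlers in year 1 under this seed; breeding not exercised")
  }
})

test_that("disperser energy never exceeds the ceiling along a whole trace", {
  land <- homog_landscape(L = 2000, release = small_release,
                          p_capture = 1, size_mean = 50, size_sd = 10,
                          energy_cost = 1)
  cfg <- small_run_cfg(trigger_threshold = 1e6)
  res <- run_simulation(cfg, land)
  expect_true(all(res$log$energy <= 200 + 1e-12))
})
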