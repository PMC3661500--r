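# Settlement trigger, candidate scoring, range-polygon generation and
# same-sex exclusive settlement.

test_that("the trigger fires on active-step or distinct-site counts", {
  a <- new_disperser(1, "male", c(0, 0), 100, 0, 200)
  a$steps_taken <- 167L
  expect_false(trigger_reached(a, "steps", 168))
  a$steps_taken <- 168L
  expect_true(trigger_reached(a, "steps", 168))    # raccoon trigger time
  a$sites_visited <- 999L
  expect_false(trigger_reached(a, "sites", 1000))
  a$sites_visited <- 1000L
  expect_true(trigger_reached(a, "sites", 1000))   # chipmunk trigger
})

test_that("a single candidate is always chosen", {
  set.seed(51)
  cand <- data.frame(x = 1, y = 2, dist = 100, food_quality = 0.5,
                     risk_quality = 0.9)
  for (cr in c("closest", "food", "risk", "integrated")) {
    pick <- score_candidates(cand, cr, 500)
    expect_equal(pick$x, 1)
  }
  expect_null(score_candidates(cand[0, ], "closest", 500))
})

test_that("a huge distance weighting factor negates proximity", {
  set.seed(52)
  # equal quality, wildly different distances: with w = 1e9 selection is
  # uniform across candidates
  cand <- data.frame(x = 1:4, y = 0, dist = c(10, 1e3, 1e5, 5e5),
                     food_quality = 1, risk_quality = 1)
  picks <- replicate(8000, score_candidates(cand, "integrated", 1e9)$x)
  freq <- tabulate(picks, 4) / 8000
  expect_true(all(abs(freq - 0.25) < 0.02))
  chi <- sum((tabulate(picks, 4) - 2000)^2 / 2000)
  expect_lt(chi, qchisq(0.999, df = 3))
})

test_that("selection odds follow Q * exp(-d/w)", {
  set.seed(53)
  d <- 700
  cand <- data.frame(x = 1:2, y = 0, dist = c(d, 2 * d),
                     food_quality = 1, risk_quality = 1)
  picks <- replicate(1e4, score_candidates(cand, "closest", d)$x)
  p1 <- mean(picks == 1)
  expect_equal(p1, exp(-1) / (exp(-1) + exp(-2)), tolerance = 0.02 / 0.731)
})

test_that("quality weighting prefers better food and lower risk", {
  set.seed(54)
  cand <- data.frame(x = 1:2, y = 0, dist = c(100, 100),
                     food_quality = c(4, 1), risk_quality = c(0.5, 1))
  pf <- mean(replicate(4000, score_candidates(cand, "food", 1e9)$x) == 1)
  expect_equal(pf, 0.8, tolerance = 0.05)          # 4 : 1 odds
  pr <- mean(replicate(4000, score_candidates(cand, "risk", 1e9)$x) == 1)
  expect_equal(pr, 1 / 3, tolerance = 0.1)         # 0.5 : 1 odds
})

test_that("generated range polygons attain the minimum area", {
  set.seed(55)
  # degenerate radii (cv = 0) give the regular 12-gon with exactly A_min
  p0 <- generate_polygon(c(0, 0), 4.25e6, radius_cv = 0)
  expect_equal(dispersim:::geom_area(p0), 4.25e6, tolerance = 1e-9)
  expect_equal(nrow(p0), 12L)

  # stochastic radii: every polygon simple (star-shaped) with area >= A_min
  for (a_min in c(4.25e6, 2.32e6)) {               # marten male / female
    for (k in 1:500) {
      p <- generate_polygon(c(1000, -500), a_min)
      expect_gte(dispersim:::geom_area(p), a_min)
    }
  }
  # star-shaped decomposition must cover the ring exactly
  p <- generate_polygon(c(0, 0), 1e6)
  pieces <- dispersim:::fan_pieces(p)
  expect_equal(sum(vapply(pieces, dispersim:::geom_area, numeric(1))),
               dispersim:::geom_area(p), tolerance = 1e-9)
})

test_that("settlement requires usable area and same-sex vacancy", {
  set.seed(56)
  suit <- parameter_map("suitability", list(rect_poly(0, 0, 20000, 20000)),
                        data.frame(suitable = 1, occupied_male = 0,
                                   occupied_female = 0))
  a <- new_disperser(1, "male", c(10000, 10000), 100, 0, 200)
  site <- data.frame(x = 10000, y = 10000)
  res <- attempt_settlement(a, site, suit, list(), 4.25e6, 10)
  expect_true(res$settled)
  expect_equal(res$animal$status, "settled")
  expect_gte(dispersim:::geom_area(res$range$poly), 4.25e6)

  # a second male at the same spot is excluded by the first range
  b <- new_disperser(2, "male", c(10000, 10000), 100, 0, 200)
  res2 <- attempt_settlement(b, site, suit, list(res$range$poly), 4.25e6, 11)
  expect_false(res2$settled)
  expect_equal(res2$animal$status, "dispersing")

  # a female settles over the male range (same-sex exclusion only)
  fem <- new_disperser(3, "female", c(10000, 10000), 100, 0, 200)
  res3 <- attempt_settlement(fem, site, suit, list(), 2.32e6, 12)
  expect_true(res3$settled)
  expect_gt(range_overlap_area(res3$range$poly, res$range$poly), 0)

  # unsuitable habitat rejects settlement outright
  bad <- parameter_map("suitability", list(rect_poly(0, 0, 20000, 20000)),
                       data.frame(suitable = 0, occupied_male = 0,
                                  occupied_female = 0))
  c2 <- new_disperser(4, "male", c(10000, 10000), 100, 0, 200)
  expect_false(attempt_settlement(c2, site, bad, list(), 4.25e6, 13)$settled)
})

test_that("a rejected site is remembered as ineligible", {
  set.seed(57)
  suit <- parameter_map("suitability", list(rect_poly(0, 0, 100, 100)),
                        data.frame(suitable = 0, occupied_male = 0,
                                   occupied_female = 0))
  a <- new_disperser(1, "male", c(50, 50), 100, 0, 200)
  n0 <- a$memory$n
  res <- attempt_settlement(a, data.frame(x = 50, y = 50), suit, list(),
                            1e3, 5)
  expect_false(res$settled)
  expect_gt(res$animal$memory$n, n0)
  st <- memory_status(res$animal$memory, c(50, 50))
  expect_equal(st$suitable, 0)
})

test_that("occupancy flags follow settlements and removals", {
  set.seed(58)
  suit <- two_cell_map("suitability",
                       data.frame(suitable = c(1, 1), occupied_male = c(0, 0),
                                  occupied_female = c(0, 0)))
  poly <- generate_polygon(c(250, 500), 1e4)
  suit2 <- apply_occupancy(suit, poly, "male", 1)
  expect_equal(suit2$attrs$occupied_male[1], 1)
  expect_equal(suit2$attrs$occupied_female[1], 0)
  suit3 <- apply_occupancy(suit2, poly, "male", 0)
  expect_equal(suit3$attrs$occupied_male[1], 0)
})

test_that("season close kills every animal still dispersing", {
  a <- new_disperser(1, "male", c(0, 0), 100, 0, 200)
  b <- new_disperser(2, "female", c(0, 0), 100, 0, 200)
  b$status <- "settled"
  out <- end_of_season(list(a, b))
  expect_equal(out[[1]]$status, "dead")
  expect_equal(out[[1]]$cause, "season_end")
  expect_equal(out[[2]]$status, "settled")   # settlers unaffected
})
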