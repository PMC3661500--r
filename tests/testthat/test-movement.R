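# Correlated-random-walk draws, boundary permeability, path construction
# and the perceptual window.

test_that("wrapped-Cauchy turning matches its closed-form resultant length", {
  set.seed(31)
  n <- 1e5
  # rho = 1: heading preserved exactly
  expect_identical(sample_turn_angle(0.7, 1), 0.7)
  # rho = 0: uniform turning; resultant of n draws ~ n^(-1/2)
  th0 <- replicate(n, sample_turn_angle(0, 0))
  r0 <- sqrt(mean(cos(th0))^2 + mean(sin(th0))^2)
  expect_lt(r0, 0.01)
  # rho = 0.6: E[cos theta] = rho
  th6 <- replicate(n, sample_turn_angle(0, 0.6))
  expect_equal(mean(cos(th6)), 0.6, tolerance = 0.01 / 0.6)
  expect_true(all(th6 > -pi & th6 <= pi))
})

test_that("step lengths are truncated normal with the requested moments", {
  set.seed(32)
  expect_identical(sample_step_length(100, 0), 100)
  expect_identical(sample_step_length(0, 0), 0)
  x <- replicate(1e5, sample_step_length(100, 10))
  expect_equal(mean(x), 100, tolerance = 0.2 / 100)
  expect_true(all(x >= 0))
})

test_that("crossing probability is q_to / (q_from + q_to)", {
  set.seed(33)
  # impassable destination: never crossed
  expect_true(all(!replicate(200, crossing_decision(2, 0))))
  # rank-0 origin: always left
  expect_true(all(replicate(200, crossing_decision(0, 1))))
  expect_error(crossing_decision(0, 0), class = "dispersim_state_error")
  # equal ranks: 50 %
  f_eq <- mean(replicate(1e4, crossing_decision(3, 3)))
  expect_equal(f_eq, 0.5, tolerance = 0.01 / 0.5)
  # 1 vs 3: 75 %
  f_13 <- mean(replicate(1e4, crossing_decision(1, 3)))
  expect_equal(f_13, 0.75, tolerance = 0.01 / 0.75)
})

test_that("a step on a homogeneous map is the exact polar displacement", {
  m <- homog_maps(L = 1000, tortuosity = 1, step_mean = 100, step_sd = 0)$movement
  eff <- make_eff(tortuosity = 1, step_mean = 100, step_sd = 0)
  p <- advance(c(500, 500), 0.3, m, eff)
  expect_equal(p$terminus, c(500 + 100 * cos(0.3), 500 + 100 * sin(0.3)),
               tolerance = 1e-12)
  expect_false(p$truncated_by_boundary)
  expect_equal(p$length_realized, 100)
})

test_that("a step into an impassable polygon truncates at the shared boundary", {
  set.seed(34)
  m <- quad_movement_map(crossing = c(1, 0, 1, 1))  # right-bottom cell sealed
  eff <- make_eff(tortuosity = 1, step_mean = 300, step_sd = 0)
  # aim straight right from the left-bottom cell into the sealed cell
  p <- advance(c(300, 250), 0, m, eff)
  expect_true(p$truncated_by_boundary)
  expect_equal(p$terminus[1], 500, tolerance = 1e-6)
  expect_equal(p$terminus[2], 250, tolerance = 1e-9)
  expect_lt(p$length_realized, 300)
})

test_that("empirical boundary-crossing frequencies match the odds formula", {
  set.seed(35)
  m <- quad_movement_map(crossing = c(1, 2, 3, 4), step_mean = 220, step_sd = 0,
                         tortuosity = 0)
  eff <- make_eff(tortuosity = 0, step_mean = 220, step_sd = 0)
  # every boundary decision along each walk is recorded on the path object
  attempts <- matrix(0, 4, 4); crossed <- matrix(0, 4, 4)
  loc <- c(450, 250); h <- 0
  for (i in 1:3000) {
    p <- advance(loc, h, m, eff)
    for (d in p$decisions) {
      attempts[d["from"], d["to"]] <- attempts[d["from"], d["to"]] + 1
      crossed[d["from"], d["to"]] <- crossed[d["from"], d["to"]] + d["crossed"]
    }
    loc <- p$terminus; h <- p$heading_out
  }
  q <- c(1, 2, 3, 4)
  checked <- 0L
  for (a in 1:4) for (b in 1:4) {
    n <- attempts[a, b]
    if (n < 50) next
    pexp <- q[b] / (q[a] + q[b])
    se <- sqrt(pexp * (1 - pexp) / n)
    expect_lt(abs(crossed[a, b] / n - pexp), 3 * se)
    checked <- checked + 1L
  }
  expect_gte(checked, 4L)   # several boundary pairs actually exercised
})

test_that("trajectories stay inside the extent under edge reflection", {
  set.seed(36)
  m <- homog_maps(L = 500, tortuosity = 0, step_mean = 120, step_sd = 30)$movement
  eff <- make_eff(tortuosity = 0, step_mean = 120, step_sd = 30)
  loc <- c(490, 490); h <- 0.7   # hugging a corner
  for (i in 1:20000) {
    p <- advance(loc, h, m, eff)
    loc <- p$terminus; h <- p$heading_out
    if (loc[1] < 0 || loc[1] > 500 || loc[2] < 0 || loc[2] > 500) break
  }
  expect_true(loc[1] >= 0 && loc[1] <= 500 && loc[2] >= 0 && loc[2] <= 500)
})

test_that("realized displacement never exceeds the drawn step length", {
  set.seed(37)
  m <- quad_movement_map(crossing = c(1, 2, 3, 4), tortuosity = 0)
  eff <- make_eff(tortuosity = 0, step_mean = 200, step_sd = 50)
  loc <- c(500, 500); h <- 0
  for (i in 1:2000) {
    p <- advance(loc, h, m, eff)
    expect_lte(p$length_realized, p$length_drawn + 1e-9)
    disp <- sqrt(sum((p$terminus - p$origin)^2))
    expect_lte(disp, p$length_drawn + 1e-9)
    loc <- p$terminus; h <- p$heading_out
  }
})

test_that("rho = 1 with zero sd walks a straight line", {
  m <- homog_maps(L = 1e6, tortuosity = 1, step_mean = 100, step_sd = 0)$movement
  eff <- make_eff(tortuosity = 1, step_mean = 100, step_sd = 0)
  loc <- c(5e5, 5e5); h <- 0.987
  pts <- matrix(NA_real_, 50, 2)
  for (i in 1:50) {
    p <- advance(loc, h, m, eff)
    loc <- p$terminus; h <- p$heading_out
    pts[i, ] <- loc
  }
  d0 <- pts[1, ] - c(5e5, 5e5)
  for (i in 2:50) {
    di <- pts[i, ] - c(5e5, 5e5)
    cross <- d0[1] * di[2] - d0[2] * di[1]
    expect_lt(abs(cross) / (sqrt(sum(d0^2)) * sqrt(sum(di^2))), 1e-9)
  }
})

test_that("a rho = 0 walk has linear net squared displacement", {
  set.seed(38)
  m <- homog_maps(L = 1e6, tortuosity = 0, step_mean = 10, step_sd = 2)$movement
  eff <- make_eff(tortuosity = 0, step_mean = 10, step_sd = 2)
  nrep <- 300; nstep <- 40
  r2 <- numeric(nrep)
  for (r in 1:nrep) {
    loc <- c(5e5, 5e5); h <- runif(1, -pi, pi)
    for (i in 1:nstep) {
      p <- advance(loc, h, m, eff)
      loc <- p$terminus; h <- p$heading_out
    }
    r2[r] <- sum((loc - c(5e5, 5e5))^2)
  }
  slope <- mean(r2) / nstep
  expect_equal(slope, 10^2 + 2^2, tolerance = 0.15)  # Monte-Carlo error
})

test_that("the perceptual window has the stadium closed-form area", {
  seg <- list(pieces = list(list(p0 = c(0, 0), p1 = c(100, 0))))
  reg <- perception_polygon(seg, 120)
  a <- sum(vapply(reg, dispersim:::geom_area, numeric(1)))
  expect_equal(a, 2 * 120 * 100 + pi * 120^2, tolerance = 0.005)

  # zero-length segment buffers to a disc
  seg0 <- list(pieces = list(list(p0 = c(3, 4), p1 = c(3, 4))))
  reg0 <- perception_polygon(seg0, 100)   # marten baseline window
  a0 <- sum(vapply(reg0, dispersim:::geom_area, numeric(1)))
  expect_equal(a0, pi * 100^2, tolerance = 0.005)

  expect_length(perception_polygon(seg, 0), 0L)
})
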