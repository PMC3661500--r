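# Simulation engine: configuration, the per-step pipeline, geographic animal
# ordering, and the season/year loop under a single seeded random stream.

#' Build and validate a simulation configuration
#'
#' Collects the time model, species attributes, behaviour-state settings,
#' home-range rules and demography into one validated object.
#'
#' @param years number of simulated years (>= 1).
#' @param season_days days in each dispersal season (>= 1).
#' @param step_minutes time-step length in minutes (>= 1).
#' @param start_hour hour of day dispersal begins (0-23).
#' @param scenario `"release_only"`, `"residents_only"` or `"combined"`.
#' @param energy_init,energy_min,energy_max disperser energy bounds
#'   (starvation strictly below `energy_min`, gains clamp at `energy_max`).
#' @param forage_threshold energy level below which animals switch from
#'   searching to foraging; `NULL` disables activity-mode switching.
#' @param perception_window baseline perception radius in metres.
#' @param p_risky_to_safe,p_safe_to_risky per-step vigilance switch
#'   probabilities.
#' @param active_mean,active_sd,rest_mean,rest_sd activity/rest bout
#'   durations in hours; the active+rest means must divide 24.  A zero
#'   `rest_mean` (with zero sd) means animals are active every step.
#' @param trigger_mode `"steps"` or `"sites"`; `trigger_threshold` the
#'   count of active steps (or distinct suitable unoccupied sites) before
#'   home-range selection begins.
#' @param hr_criterion home-range selection criterion (`"closest"`,
#'   `"food"`, `"risk"`, `"integrated"`).
#' @param hr_w distance weighting factor in metres, a single value or
#'   `list(male=, female=)`; large values make proximity irrelevant.
#' @param hr_min_area minimum home-range area in m2, `list(male=, female=)`.
#' @param n_candidates candidate sites drawn from memory per settlement
#'   attempt (default 30).
#' @param resident_p_step per-time-step aspatial resident mortality.
#' @param p_inter inter-dispersal resident mortality.
#' @param p_pregnant,litter_mean,litter_sd,p_female breeding parameters.
#' @param modifiers a [modifier_set()]; `use_modifiers = FALSE` bypasses
#'   the modifier machinery entirely (the baseline, equivalent to all
#'   multipliers 1).
#' @param residents optional roster data frame (`x`, `y`, `sex`) of initial
#'   resident home-range centres for resident scenarios.
#' @param record_corridors keep per-step perception corridors for vector
#'   output (default `TRUE`; disable to save memory on large runs).
#' @param seed integer seed for the single global random stream.
#' @return a validated `dispersim_config` list.
#' @export
sim_config <- function(years = 1, season_days = 30, step_minutes = 60,
                       start_hour = 0,
                       scenario = "release_only",
                       energy_init = 100, energy_min = 0, energy_max = 200,
                       forage_threshold = NULL,
                       perception_window = 100,
                       p_risky_to_safe = 0, p_safe_to_risky = 0,
                       active_mean = 24, active_sd = 0,
                       rest_mean = 0, rest_sd = 0,
                       trigger_mode = "steps", trigger_threshold = 100,
                       hr_criterion = "closest", hr_w = 1000,
                       hr_min_area = list(male = 1e5, female = 1e5),
                       n_candidates = 30,
                       resident_p_step = 0, p_inter = 0,
                       p_pregnant = 0, litter_mean = 0, litter_sd = 0,
                       p_female = 0.5,
                       modifiers = modifier_set(), use_modifiers = TRUE,
                       residents = NULL,
                       record_corridors = TRUE,
                       seed = 1L) {
  stopifnot(years >= 1, season_days >= 1, step_minutes >= 1,
            start_hour >= 0, start_hour <= 23)
  scenario <- match.arg(scenario, c("release_only", "residents_only", "combined"))
  trigger_mode <- match.arg(trigger_mode, c("steps", "sites"))
  hr_criterion <- match.arg(hr_criterion, c("closest", "food", "risk", "integrated"))
  if (!(energy_min < energy_init && energy_init <= energy_max)) {
    .stop_cfg("energy bounds must satisfy min < initial <= max")
  }
  for (p in c(p_risky_to_safe, p_safe_to_risky, resident_p_step, p_inter,
              p_pregnant, p_female)) {
    if (p < 0 || p > 1) .stop_cfg("probabilities must lie in [0, 1]")
  }
  stopifnot(perception_window >= 0, trigger_threshold >= 1, n_candidates >= 1,
            litter_sd >= 0)
  if (!is.list(hr_w)) hr_w <- list(male = hr_w, female = hr_w)
  stopifnot(hr_w$male > 0, hr_w$female > 0)
  stopifnot(is.list(hr_min_area), hr_min_area$male > 0, hr_min_area$female > 0)
  if (rest_mean > 0 || rest_sd > 0) {
    cycle <- active_mean + rest_mean
    if (abs(24 / cycle - round(24 / cycle)) > 1e-9) {
      .stop_cfg("active_mean + rest_mean (", cycle, " h) must divide 24 h")
    }
  }
  if (!inherits(modifiers, "dispersim_modifiers")) {
    modifiers <- modifier_set(modifiers)
  }
  structure(list(
    years = as.integer(years), season_days = as.integer(season_days),
    step_minutes = as.numeric(step_minutes), start_hour = as.numeric(start_hour),
    scenario = scenario,
    energy_init = energy_init, energy_min = energy_min, energy_max = energy_max,
    forage_threshold = forage_threshold,
    perception_window = perception_window,
    p_risky_to_safe = p_risky_to_safe, p_safe_to_risky = p_safe_to_risky,
    active_mean = active_mean, active_sd = active_sd,
    rest_mean = rest_mean, rest_sd = rest_sd,
    trigger_mode = trigger_mode, trigger_threshold = as.integer(trigger_threshold),
    hr_criterion = hr_criterion, hr_w = hr_w, hr_min_area = hr_min_area,
    n_candidates = as.integer(n_candidates),
    resident_p_step = resident_p_step, p_inter = p_inter,
    p_pregnant = p_pregnant, litter_mean = litter_mean, litter_sd = litter_sd,
    p_female = p_female,
    modifiers = modifiers, use_modifiers = isTRUE(use_modifiers),
    residents = residents,
    record_corridors = isTRUE(record_corridors),
    seed = as.integer(seed)
  ), class = "dispersim_config")
}

#' Order animals geographically and reassign ids
#'
#' At the beginning of each year animal numbers are assigned by start
#' location, north to south with west-of ties first, and processing follows
#' id order for the whole season; the result is independent of input order.
#'
#' @param dispersers list of `dispersim_disperser`.
#' @return the list sorted with ids reassigned 1..n.
#' @export
order_animals <- function(dispersers) {
  if (!length(dispersers)) return(dispersers)
  ys <- vapply(dispersers, function(a) a$loc[2], numeric(1))
  xs <- vapply(dispersers, function(a) a$loc[1], numeric(1))
  o <- order(-ys, xs)
  out <- dispersers[o]
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

# --- step-log collector (environment with growable column vectors) ---------

.log_new <- function() {
  lg <- new.env(parent = emptyenv())
  lg$n <- 0L
  lg$cap <- 1024L
  lg$year <- integer(1024L); lg$day <- integer(1024L); lg$step <- integer(1024L)
  lg$id <- integer(1024L); lg$sex <- character(1024L)
  lg$x <- numeric(1024L); lg$y <- numeric(1024L); lg$energy <- numeric(1024L)
  lg$active <- logical(1024L); lg$activity <- character(1024L)
  lg$vigilance <- character(1024L); lg$status <- character(1024L)
  lg$cause <- character(1024L); lg$settled <- logical(1024L)
  lg
}

.log_push <- function(lg, year, day, step, id, sex, x, y, energy, active,
                      activity, vigilance, status, cause, settled) {
  n <- lg$n + 1L
  if (n > lg$cap) {
    cap <- 2L * lg$cap
    for (f in c("year", "day", "step", "id", "sex", "x", "y", "energy",
                "active", "activity", "vigilance", "status", "cause", "settled")) {
      length(lg[[f]]) <- cap
    }
    lg$cap <- cap
  }
  lg$n <- n
  lg$year[n] <- year; lg$day[n] <- day; lg$step[n] <- step
  lg$id[n] <- id; lg$sex[n] <- sex
  lg$x[n] <- x; lg$y[n] <- y; lg$energy[n] <- energy
  lg$active[n] <- active; lg$activity[n] <- activity
  lg$vigilance[n] <- vigilance; lg$status[n] <- status
  lg$cause[n] <- cause; lg$settled[n] <- settled
  invisible(lg)
}

.log_collect <- function(lg) {
  i <- seq_len(lg$n)
  data.frame(year = lg$year[i], day = lg$day[i], step = lg$step[i],
             id = lg$id[i], sex = lg$sex[i], x = lg$x[i], y = lg$y[i],
             energy = lg$energy[i], active = lg$active[i],
             activity = lg$activity[i], vigilance = lg$vigilance[i],
             status = lg$status[i], cause = lg$cause[i],
             settled = lg$settled[i])
}

# --- the per-step pipeline --------------------------------------------------

#' Advance one animal through one time-step
#'
#' Runs the fixed sub-step pipeline: (1) bout check (resting animals log a
#' row and stop); (2) modifier resolution at the origin polygon; (3)
#' vigilance draw; (4) activity-mode check against the forage/search
#' threshold; (5) movement with boundary decisions; (6) energy cost; (7)
#' foraging gain; (8) starvation check; (9) predation draw; (10) perception
#' corridor, memory update and site counting; (11) settlement attempt when
#' the trigger is reached.  A death short-circuits the remaining stages, so
#' every animal carries exactly one cause of death.
#'
#' @param animal a dispersing `dispersim_disperser`.
#' @param state the engine state environment of the running simulation
#'   (active maps, registry, clock, log); created by [run_simulation()].
#' @return the updated animal; the state environment is modified in place
#'   (log row appended, registry/occupancy updated on settlement).
#' @export
step_animal <- function(animal, state) {
  cfg <- state$cfg
  logrow <- function(a, active) {
    .log_push(state$log, state$year, state$day, state$k, a$id, a$sex,
              a$loc[1], a$loc[2], a$energy, active, a$activity, a$vigilance,
              a$status, if (is.na(a$cause)) "" else a$cause,
              identical(a$status, "settled"))
  }

  # (1) bout check
  if (!is.null(animal$bouts) && !is_active(animal$bouts, state$t_wall)) {
    logrow(animal, FALSE)
    return(animal)
  }

  # (2) resolve modifiers at the origin polygon
  mv <- attrs_at(state$move, animal$loc)
  fd <- attrs_at(state$food, animal$loc)
  rk <- attrs_at(state$risk, animal$loc)
  stt <- paste(animal$vigilance, animal$activity, sep = "-")
  eff <- if (cfg$use_modifiers) {
    resolve_params(mv, fd, rk, cfg$modifiers, animal$sex, stt,
                   state$hour, state$day, cfg$perception_window)
  } else {
    structure(list(
      p_capture = min(max(fd$p_capture, 0), 1),
      p_mortality = min(max(rk$p_mortality, 0), 1),
      energy_cost = max(mv$energy_cost, 0),
      step_mean = max(mv$step_mean, 0), step_sd = max(mv$step_sd, 0),
      tortuosity = min(max(mv$tortuosity, 0), 1), crossing = mv$crossing,
      perception_radius = max(cfg$perception_window * mv$perception_mod, 0)
    ), class = "dispersim_effective")
  }

  # (3) vigilance draw
  animal$vigilance <- update_vigilance(animal$vigilance,
                                       cfg$p_risky_to_safe, cfg$p_safe_to_risky)
  # (4) activity mode from energy threshold
  animal$activity <- update_activity_mode(animal$energy, cfg$forage_threshold)

  # (5) movement
  path <- advance(animal$loc, animal$heading, state$move, eff)
  animal$loc <- path$terminus
  animal$heading <- path$heading_out
  animal$steps_taken <- animal$steps_taken + 1L

  # (6)-(8) energy ledger and starvation
  gain <- forage(eff, fd)
  animal <- apply_energy(animal, eff$energy_cost, gain)
  if (identical(animal$status, "dead")) {
    animal$death_step <- state$k
    logrow(animal, TRUE)
    return(animal)
  }

  # (9) predation
  if (predation_draw(eff)) {
    animal$status <- "dead"
    animal$cause <- "predation"
    animal$death_loc <- animal$loc
    animal$death_step <- state$k
    logrow(animal, TRUE)
    return(animal)
  }

  # (10) perception, memory, site counting.  Perception is patch-granular:
  # a suitability polygon intersected by the corridor is remembered whole,
  # with its current status, and re-remembered only when that status
  # changes (per-feature cache) — keeping memory size bounded by the
  # number of patches rather than the number of steps.
  corridor <- perception_polygon(path, eff$perception_radius)
  if (length(corridor)) {
    suit <- state$suit
    scode <- suit$attrs$suitable + 2 * suit$attrs$occupied_male +
      4 * suit$attrs$occupied_female
    for (piece in corridor) {
      pb <- geom_bbox(piece)
      b <- suit$bboxes
      cand <- which(b[, 1] <= pb[3] & b[, 3] >= pb[1] &
                    b[, 2] <= pb[4] & b[, 4] >= pb[2])
      for (i in cand) {
        if (animal$mem_feat[i] == scode[i]) next
        clp <- clip_convex(suit$polys[[i]], piece)
        if (is.null(clp)) next
        remember(animal$memory, suit$polys[[i]],
                 list(suitable = suit$attrs$suitable[i],
                      occupied_male = suit$attrs$occupied_male[i],
                      occupied_female = suit$attrs$occupied_female[i]),
                 state$t_abs)
        animal$mem_feat[i] <- scode[i]
      }
    }
    if (cfg$record_corridors) {
      key <- paste0(state$year, "_", animal$id)
      state$corridors[[key]] <- c(state$corridors[[key]], corridor)
    }
  }
  sf <- locate_feature(state$suit, animal$loc)
  if (!is.na(sf) && !(sf %in% animal$visited_features)) {
    occf <- if (identical(animal$sex, "male")) "occupied_male" else "occupied_female"
    if (state$suit$attrs$suitable[sf] == 1 && state$suit$attrs[[occf]][sf] == 0) {
      animal$visited_features <- c(animal$visited_features, sf)
      animal$sites_visited <- animal$sites_visited + 1L
    }
  }

  # (11) settlement attempt
  if (trigger_reached(animal, cfg$trigger_mode, cfg$trigger_threshold)) {
    pts <- candidate_points(animal$memory, animal$sex, cfg$n_candidates)
    if (nrow(pts)) {
      fq <- numeric(nrow(pts)); rq <- numeric(nrow(pts))
      for (i in seq_len(nrow(pts))) {
        fa <- attrs_at(state$food, pts[i, ])
        ra <- attrs_at(state$risk, pts[i, ])
        fq[i] <- fa$p_capture * fa$size_mean
        rq[i] <- 1 - ra$p_mortality
      }
      cand <- data.frame(x = pts[, 1], y = pts[, 2],
                         dist = sqrt((pts[, 1] - animal$loc[1])^2 +
                                     (pts[, 2] - animal$loc[2])^2),
                         food_quality = fq, risk_quality = rq)
      site <- score_candidates(cand, cfg$hr_criterion, cfg$hr_w[[animal$sex]])
      animal$loc <- c(site$x[1], site$y[1])   # relocate to the chosen site
      same_sex <- lapply(Filter(function(r) identical(r$sex, animal$sex),
                                state$registry), `[[`, "poly")
      res <- attempt_settlement(animal, site, state$suit, same_sex,
                                cfg$hr_min_area[[animal$sex]], state$t_abs)
      animal <- res$animal
      if (res$settled) {
        animal$settled_step <- state$k
        rng <- res$range
        rng$year <- state$year
        state$registry[[length(state$registry) + 1L]] <- rng
        state$suit <- apply_occupancy(state$suit, rng$poly, animal$sex, 1)
      }
    }
  }

  logrow(animal, TRUE)
  animal
}

# precomputed swap lookup: for each role, sorted event times and maps
.swap_index <- function(land) {
  idx <- list()
  for (r in .map_roles) {
    ev <- Filter(function(s) identical(s$role, r), land$swaps)
    if (length(ev)) {
      at <- vapply(ev, `[[`, numeric(1), "at")
      o <- order(at)
      idx[[r]] <- list(at = at[o], maps = lapply(ev[o], `[[`, "map"))
    }
  }
  idx
}

.swap_lookup <- function(idx, land, role, t_abs) {
  e <- idx[[role]]
  if (is.null(e)) return(land$maps[[role]])
  i <- findInterval(t_abs, e$at)
  if (i < 1) land$maps[[role]] else e$maps[[i]]
}

#' Run a full simulation
#'
#' Executes the season/year loop: each year animals are ordered
#' geographically; each time-step the active maps are looked up (applying
#' any due swap events), residents face aspatial step mortality (freed
#' ranges become available the same step), and every disperser runs the
#' per-step pipeline in id order; at season close unsettled animals die,
#' settled animals join the resident roster; the inter-dispersal period is
#' a single discrete event of resident survival and breeding whose
#' offspring are the next season's dispersers, starting at their mother's
#' range centre.
#'
#' @param cfg a `dispersim_config`.
#' @param land a `dispersim_landscape`.
#' @return a `dispersim_result` list: `log` (per animal-step data frame),
#'   `animals` (per animal-year fate records), `ranges` (all home ranges
#'   with owner, sex, year), `corridors` (perception polygons per
#'   animal-year, if recorded), `n_steps_season`, `config`.
#' @export
run_simulation <- function(cfg, land) {
  stopifnot(inherits(cfg, "dispersim_config"), inherits(land, "dispersim_landscape"))
  set.seed(cfg$seed)
  pop <- initialize_population(land, cfg$scenario, cfg)
  residents <- pop$residents
  dispersers <- pop$dispersers

  state <- new.env(parent = emptyenv())
  state$cfg <- cfg
  state$log <- .log_new()
  state$corridors <- list()
  state$registry <- lapply(residents, `[[`, "range")
  swaps <- .swap_index(land)

  # initial occupancy flags from resident ranges
  suit0 <- land$maps$suitability
  for (rng in state$registry) suit0 <- apply_occupancy(suit0, rng$poly, rng$sex, 1)
  occupancy_sync <- function(m) {
    for (rng in state$registry) m <- apply_occupancy(m, rng$poly, rng$sex, 1)
    m
  }

  n_steps <- as.integer(floor(cfg$season_days * 1440 / cfg$step_minutes))
  fates <- list()
  use_bouts <- cfg$rest_mean > 0 || cfg$rest_sd > 0

  for (year in seq_len(cfg$years)) {
    state$year <- year
    dispersers <- order_animals(dispersers)
    horizon <- cfg$season_days * 1440
    state$suit <- if (year == 1) suit0 else occupancy_sync(land$maps$suitability)
    cur_suit_src <- "initial"
    for (i in seq_along(dispersers)) {
      a <- dispersers[[i]]
      a$vigilance <- "risky"               # every season starts risky
      a$heading <- stats::runif(1, -pi, pi)
      a$visited_features <- integer(0)
      a$mem_feat <- rep(-1L, length(state$suit$polys))
      a$bouts <- if (use_bouts) {
        schedule_bouts(cfg$active_mean, cfg$active_sd, cfg$rest_mean,
                       cfg$rest_sd, cfg$start_hour, horizon, cfg$step_minutes)
      } else NULL
      dispersers[[i]] <- a
    }

    for (k in seq_len(n_steps) - 1L) {
      t_wall <- cfg$start_hour * 60 + k * cfg$step_minutes
      t_abs <- (year - 1) * cfg$season_days * 1440 + t_wall
      state$k <- k + 1L
      state$t_wall <- t_wall
      state$t_abs <- t_abs
      state$hour <- (t_wall %% 1440) / 60
      state$day <- min(t_wall %/% 1440 + 1L, cfg$season_days)
      state$move <- .swap_lookup(swaps, land, "movement", t_abs)
      state$food <- .swap_lookup(swaps, land, "food", t_abs)
      state$risk <- .swap_lookup(swaps, land, "risk", t_abs)
      suit_now <- .swap_lookup(swaps, land, "suitability", t_abs)
      src <- if (is.null(swaps$suitability)) "initial" else {
        as.character(findInterval(t_abs, swaps$suitability$at))
      }
      if (!identical(src, cur_suit_src)) {   # re-flag occupancy on a swapped map
        state$suit <- occupancy_sync(suit_now)
        cur_suit_src <- src
        for (i in seq_along(dispersers)) {   # feature ids changed: re-perceive
          dispersers[[i]]$mem_feat <- rep(-1L, length(state$suit$polys))
        }
      }

      if (length(residents) && cfg$resident_p_step > 0) {
        rm <- resident_step_mortality(residents, cfg$resident_p_step)
        residents <- rm$residents
        if (length(rm$freed)) {
          keep <- vapply(state$registry, function(r)
            !any(vapply(rm$freed, function(f)
              identical(f$poly, r$poly), logical(1))), logical(1))
          state$registry <- state$registry[keep]
          for (f in rm$freed) {
            state$suit <- apply_occupancy(state$suit, f$poly, f$sex, 0)
          }
          state$suit <- occupancy_sync(state$suit)  # restore overlapping flags
        }
      }

      if (length(dispersers)) {
        for (i in seq_along(dispersers)) {
          a <- dispersers[[i]]
          if (identical(a$status, "dispersing")) {
            dispersers[[i]] <- step_animal(a, state)
          }
        }
      }
    }

    dispersers <- end_of_season(dispersers)

    for (a in dispersers) {
      fates[[length(fates) + 1L]] <- data.frame(
        year = year, id = a$id, sex = a$sex,
        natal_x = a$natal_origin[1], natal_y = a$natal_origin[2],
        status = a$status, cause = if (is.na(a$cause)) "" else a$cause,
        settled_step = if (is.na(a$settled_step)) NA_integer_ else a$settled_step,
        energy_init = a$energy_init, energy_final = a$energy,
        range_x = if (is.null(a$range)) NA_real_ else a$range$center[1],
        range_y = if (is.null(a$range)) NA_real_ else a$range$center[2],
        dispersal_distance = if (is.null(a$range)) NA_real_ else
          sqrt(sum((a$range$center - a$natal_origin)^2))
      )
    }

    # settled dispersers become residents for the following seasons
    for (a in dispersers) {
      if (identical(a$status, "settled")) {
        residents[[length(residents) + 1L]] <- list(
          id = length(residents) + 1L, sex = a$sex, range = a$range)
      }
    }

    if (year < cfg$years) {
      sv <- interdispersal_survival(residents, cfg$p_inter)
      residents <- sv$residents
      state$registry <- lapply(residents, `[[`, "range")
      females <- Filter(function(r) identical(r$sex, "female"), residents)
      dispersers <- breed(females, cfg$p_pregnant, cfg$litter_mean,
                          cfg$litter_sd, cfg$p_female, cfg)
    }
  }

  structure(list(
    log = .log_collect(state$log),
    animals = if (length(fates)) do.call(rbind, fates) else NULL,
    ranges = state$registry,
    corridors = state$corridors,
    residents = residents,
    n_steps_season = n_steps,
    config = cfg
  ), class = "dispersim_result")
}

#' @export
print.dispersim_result <- function(x, ...) {
  cat("<dispersim_result>", nrow(x$log), "log rows |",
      length(x$ranges), "home range(s) |",
      if (is.null(x$animals)) 0L else nrow(x$animals), "animal-year record(s)\n")
  invisible(x)
}
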