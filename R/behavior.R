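# Behavioural-state machinery: multiplicative modifiers, the
# searching/foraging activity mode, the risky/safe vigilance mode, and
# activity/rest bout scheduling.

.mod_params <- c("p_capture", "p_mortality", "energy_cost", "step_mean",
                 "tortuosity", "perception")
.mod_keytypes <- c("sex", "state", "hour", "date")
.behav_states <- c("risky-searching", "risky-foraging",
                   "safe-searching", "safe-foraging")

#' Build a modifier set
#'
#' Modifiers multiply the habitat-derived baseline parameters to express
#' variation caused by sex, behavioural state (vigilance-activity
#' combination), hour of day, and date.  Any key not listed has multiplier
#' 1, so an empty modifier set is the identity.
#'
#' @param entries data frame (or NULL) with columns `parameter` (one of
#'   `p_capture`, `p_mortality`, `energy_cost`, `step_mean`, `tortuosity`,
#'   `perception`), `key_type` (`sex`, `state`, `hour`, `date`), `key`
#'   (e.g. `"male"`, `"risky-searching"`, `"18-6"` for an hour window,
#'   `"38-114"` for a day-of-season window; windows are half-open
#'   \[start, end) and hour windows may wrap midnight), and `multiplier`
#'   (real >= 0).
#' @return a `dispersim_modifiers` object.
#' @export
modifier_set <- function(entries = NULL) {
  if (is.null(entries) || !NROW(entries)) {
    entries <- data.frame(parameter = character(), key_type = character(),
                          key = character(), multiplier = numeric())
  }
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("parameter", "key_type", "key", "multiplier") %in% names(entries)))
  if (!all(entries$parameter %in% .mod_params)) {
    .stop_cfg("unknown modifier parameter: ",
              paste(setdiff(entries$parameter, .mod_params), collapse = ", "))
  }
  if (!all(entries$key_type %in% .mod_keytypes)) {
    .stop_cfg("unknown modifier key type: ",
              paste(setdiff(entries$key_type, .mod_keytypes), collapse = ", "))
  }
  if (any(entries$multiplier < 0)) .stop_cfg("modifier multipliers must be >= 0")
  structure(list(entries = entries), class = "dispersim_modifiers")
}

# window "a-b" contains v on a half-open [a, b) scale of period `period`;
# wrap-around windows (a > b) are allowed for hours
.in_window <- function(key, v, period) {
  ab <- suppressWarnings(as.numeric(strsplit(key, "-", fixed = TRUE)[[1]]))
  if (length(ab) != 2 || anyNA(ab)) .stop_cfg("bad modifier window '", key, "'")
  if (ab[1] <= ab[2]) v >= ab[1] & v < ab[2] else v >= ab[1] | v < ab[2]
}

#' Look up the combined multiplier for one parameter
#'
#' @param mods a `dispersim_modifiers` object.
#' @param parameter modified parameter name.
#' @param sex,state animal sex and behavioural state
#'   (`"risky-searching"` etc.).
#' @param hour hour of day (fractional allowed).
#' @param day day of the dispersal season (1-based).
#' @return product of all matching multipliers (1 when none match).
#' @export
modifier_value <- function(mods, parameter, sex, state, hour, day) {
  e <- mods$entries
  if (!nrow(e)) return(1)
  e <- e[e$parameter == parameter, , drop = FALSE]
  if (!nrow(e)) return(1)
  m <- 1
  for (i in seq_len(nrow(e))) {
    hit <- switch(e$key_type[i],
      sex   = identical(e$key[i], sex),
      state = identical(e$key[i], state),
      hour  = .in_window(e$key[i], hour %% 24, 24),
      date  = .in_window(e$key[i], day, Inf)
    )
    if (isTRUE(hit)) m <- m * e$multiplier[i]
  }
  m
}

#' Resolve the effective per-step parameters for an animal
#'
#' Takes the baseline attributes of the polygons the animal currently
#' occupies on the movement, food and risk maps, applies the multiplicative
#' modifiers for its sex, behavioural state, hour and date, and clamps each
#' result to its legal range (probabilities and tortuosity to \[0,1\],
#' everything else to >= 0).  The perception radius is the species baseline
#' scaled by the movement map's `perception_mod` and the `perception`
#' modifier.
#'
#' @param move_attrs,food_attrs,risk_attrs one-row attribute records from
#'   [attrs_at()] on the respective maps.
#' @param mods a `dispersim_modifiers` object.
#' @param sex `"male"` or `"female"`.
#' @param state behavioural state string (vigilance-activity).
#' @param hour hour of day; `day` day of season.
#' @param perception_base species perception window radius in metres.
#' @return list of class `dispersim_effective`: `p_capture`, `p_mortality`,
#'   `energy_cost`, `step_mean`, `step_sd`, `tortuosity`, `crossing`,
#'   `perception_radius`.
#' @export
resolve_params <- function(move_attrs, food_attrs, risk_attrs, mods, sex,
                           state, hour, day, perception_base) {
  mv <- function(p) modifier_value(mods, p, sex, state, hour, day)
  clamp01 <- function(x) min(max(x, 0), 1)
  structure(list(
    p_capture   = clamp01(food_attrs$p_capture * mv("p_capture")),
    p_mortality = clamp01(risk_attrs$p_mortality * mv("p_mortality")),
    energy_cost = max(move_attrs$energy_cost * mv("energy_cost"), 0),
    step_mean   = max(move_attrs$step_mean * mv("step_mean"), 0),
    step_sd     = max(move_attrs$step_sd, 0),
    tortuosity  = clamp01(move_attrs$tortuosity * mv("tortuosity")),
    crossing    = move_attrs$crossing,
    perception_radius =
      max(perception_base * move_attrs$perception_mod * mv("perception"), 0)
  ), class = "dispersim_effective")
}

#' Update the activity mode from the energy reserve
#'
#' Animals forage when their reserve is strictly below the forage/search
#' threshold and search otherwise; the transition is symmetric, so energies
#' oscillating around the threshold flip the mode back and forth.  A `NULL`
#' or `NA` threshold disables the mechanism (always searching).
#'
#' @param energy current energy reserve.
#' @param threshold forage/search trigger (energy units), or `NULL`.
#' @return `"foraging"` or `"searching"`.
#' @export
update_activity_mode <- function(energy, threshold) {
  if (is.null(threshold) || is.na(threshold)) return("searching")
  if (energy < threshold) "foraging" else "searching"
}

#' Update the vigilance mode with one stochastic draw
#'
#' One uniform draw per time-step; the current mode switches iff the draw
#' falls below the transition probability that applies to it.  Every
#' dispersal season starts in risky mode (the engine resets it).
#'
#' @param mode current mode, `"risky"` or `"safe"`.
#' @param p_risky_to_safe,p_safe_to_risky per-step switch probabilities.
#' @return new mode.
#' @export
update_vigilance <- function(mode, p_risky_to_safe, p_safe_to_risky) {
  stopifnot(p_risky_to_safe >= 0, p_risky_to_safe <= 1,
            p_safe_to_risky >= 0, p_safe_to_risky <= 1)
  u <- stats::runif(1)
  if (identical(mode, "risky")) {
    if (u < p_risky_to_safe) "safe" else "risky"
  } else {
    if (u < p_safe_to_risky) "risky" else "safe"
  }
}

#' Draw an activity/rest bout schedule for one animal-year
#'
#' Bouts alternate active and rest, starting active at `start_hour` on day 1
#' (animals must begin each year active).  Each bout duration is drawn from
#' a normal distribution (hours) and truncated below at one time-step.  The
#' mean active plus rest durations must divide 24 h so that the average
#' cycle is synchronised with the day, though stochastic durations let
#' individual schedules drift off the 24-h cycle.
#'
#' @param active_mean,active_sd,rest_mean,rest_sd bout durations in hours.
#' @param start_hour hour of day at which the season starts (0-23).
#' @param horizon_min schedule length to cover, in minutes from the season
#'   origin (midnight of day 1).
#' @param step_min time-step length in minutes (truncation floor).
#' @return object of class `dispersim_bouts`: boundary times (wall minutes)
#'   of alternating active/rest bouts.
#' @export
schedule_bouts <- function(active_mean, active_sd, rest_mean, rest_sd,
                           start_hour, horizon_min, step_min) {
  stopifnot(active_mean > 0, rest_mean >= 0, active_sd >= 0, rest_sd >= 0)
  cycle <- active_mean + rest_mean
  k <- 24 / cycle
  if (abs(k - round(k)) > 1e-9) {
    .stop_cfg("mean active + rest bout durations (", cycle,
              " h) must divide 24 h")
  }
  t0 <- start_hour * 60
  bounds <- t0
  state_active <- TRUE
  t <- t0
  while (t < horizon_min) {
    mu <- if (state_active) active_mean else rest_mean
    sdv <- if (state_active) active_sd else rest_sd
    dur <- if (sdv > 0) stats::rnorm(1, mu, sdv) else mu
    dur_min <- max(dur * 60, step_min)
    t <- t + dur_min
    bounds <- c(bounds, t)
    state_active <- !state_active
  }
  structure(list(bounds = bounds, start = t0), class = "dispersim_bouts")
}

#' Is the animal active at a wall-clock minute?
#'
#' @param sched a `dispersim_bouts` schedule.
#' @param t_wall minutes since midnight of day 1 of the season.
#' @return logical; `FALSE` before the season start time.
#' @export
is_active <- function(sched, t_wall) {
  if (t_wall < sched$start) return(FALSE)
  i <- findInterval(t_wall, sched$bounds)  # interval i: bout i (1-based)
  if (i < 1 || i >= length(sched$bounds)) return(i %% 2L == 1L)
  i %% 2L == 1L
}
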