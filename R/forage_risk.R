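# Energetics and mortality: foraging gains, the energy ledger with
# starvation floor and ceiling, per-step predation, and aspatial resident
# mortality during the dispersal season.

#' Draw a foraging gain for one time-step
#'
#' With probability `eff$p_capture` the animal captures a prey item whose
#' energy content is Normal(`size_mean`, `size_sd`) truncated below at 0
#' (by clamping); otherwise the gain is 0.  Prey size comes from the food
#' map; only the capture probability is subject to modifiers.
#'
#' @param eff effective parameters from [resolve_params()].
#' @param food_attrs one-row food attribute record (`size_mean`, `size_sd`).
#' @return energy gain >= 0.
#' @export
forage <- function(eff, food_attrs) {
  p <- eff$p_capture
  if (p <= 0) return(0)
  if (stats::runif(1) >= p) return(0)
  if (food_attrs$size_sd <= 0) return(max(food_attrs$size_mean, 0))
  max(stats::rnorm(1, food_attrs$size_mean, food_attrs$size_sd), 0)
}

#' Apply one step's energy cost and gain to a disperser
#'
#' The ledger update is `E <- min(E - cost + gain, E_max)`; cost and gain
#' are netted before the single starvation check, and if the result is
#' strictly below the starvation floor the animal dies of starvation at
#' this step.
#'
#' @param animal a `dispersim_disperser`.
#' @param cost,gain energy units, both >= 0.
#' @return the updated animal (status `"dead"` with cause `"starvation"`
#'   if the floor was crossed).
#' @export
apply_energy <- function(animal, cost, gain) {
  stopifnot(cost >= 0, gain >= 0)
  e <- min(animal$energy - cost + gain, animal$energy_max)
  animal$energy <- e
  if (e < animal$energy_min) {
    animal$status <- "dead"
    animal$cause <- "starvation"
    animal$death_loc <- animal$loc
  }
  animal
}

#' Per-step predation draw
#'
#' @param eff effective parameters (uses `p_mortality`).
#' @return `TRUE` if the animal dies of predation this step.
#' @export
predation_draw <- function(eff) {
  p <- eff$p_mortality
  stopifnot(p >= 0, p <= 1)
  stats::runif(1) < p
}

#' Aspatial per-step mortality of residents
#'
#' Each resident independently dies with probability `p_step` during a
#' time-step of the dispersal season, independent of location.  Freed home
#' ranges are returned so the engine can clear their occupancy flags the
#' same step.
#'
#' @param residents list of residents.
#' @param p_step per-time-step mortality probability.
#' @return list with `residents` (survivors) and `freed` (home ranges of
#'   the dead).
#' @export
resident_step_mortality <- function(residents, p_step) {
  stopifnot(p_step >= 0, p_step <= 1)
  if (!length(residents)) return(list(residents = residents, freed = list()))
  u <- stats::runif(length(residents))
  dies <- u < p_step
  list(residents = residents[!dies],
       freed = lapply(residents[dies], `[[`, "range"))
}
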