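# Inter-dispersal demography: resident survival over the period between
# dispersal seasons and reproduction that produces the next season's
# dispersers.

#' Inter-dispersal resident survival
#'
#' Each resident independently survives the inter-dispersal period with
#' probability `1 - p_inter`.  Deaths free the home ranges, whose occupancy
#' flags the engine clears before the next season.
#'
#' @param residents list of residents.
#' @param p_inter inter-dispersal mortality probability in \[0, 1\].
#' @return list with `residents` (survivors) and `freed` (ranges of the
#'   dead).
#' @export
interdispersal_survival <- function(residents, p_inter) {
  stopifnot(p_inter >= 0, p_inter <= 1)
  if (!length(residents)) return(list(residents = residents, freed = list()))
  dies <- stats::runif(length(residents)) < p_inter
  list(residents = residents[!dies],
       freed = lapply(residents[dies], `[[`, "range"))
}

#' Breed surviving resident females
#'
#' Each surviving female becomes pregnant with probability `p_pregnant`;
#' litter size is a rounded Normal(`litter_mean`, `litter_sd`) draw with
#' negative values mapped to 0 (rounding is half-away-from-zero, applied
#' before the negative-to-zero rule); each offspring is female with
#' probability `p_female`.  Offspring begin the next dispersal season at
#' the centre of the mother's home range.
#'
#' @param females list of surviving female residents.
#' @param p_pregnant,p_female probabilities in \[0, 1\].
#' @param litter_mean,litter_sd litter-size distribution (counts),
#'   `litter_sd >= 0`.
#' @param cfg a `sim_config()` supplying offspring energy bounds.
#' @return list of new `dispersim_disperser` objects (ids are provisional;
#'   the engine reassigns them geographically at season start).
#' @export
breed <- function(females, p_pregnant, litter_mean, litter_sd, p_female, cfg) {
  stopifnot(p_pregnant >= 0, p_pregnant <= 1, p_female >= 0, p_female <= 1,
            litter_sd >= 0)
  young <- list()
  for (f in females) {
    if (stats::runif(1) >= p_pregnant) next
    raw <- if (litter_sd > 0) stats::rnorm(1, litter_mean, litter_sd) else litter_mean
    litter <- sign(raw) * floor(abs(raw) + 0.5)  # round half away from zero
    litter <- max(as.integer(litter), 0L)
    if (litter < 1L) next
    for (k in seq_len(litter)) {
      sex <- if (stats::runif(1) < p_female) "female" else "male"
      young[[length(young) + 1L]] <- new_disperser(
        id = length(young) + 1L, sex = sex,
        location = f$range$center,
        energy_init = cfg$energy_init, energy_min = cfg$energy_min,
        energy_max = cfg$energy_max
      )
    }
  }
  young
}
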