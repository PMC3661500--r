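# Agent state: dispersers, residents, population initialisation under the
# three scenarios, and the perception memory map.

#' Create a disperser
#'
#' @param id integer identifier (reassigned geographically each year by the
#'   engine).
#' @param sex `"male"` or `"female"`.
#' @param location numeric length-2 starting point (also the natal origin).
#' @param energy_init,energy_min,energy_max energy bounds: starting reserve,
#'   starvation floor (death strictly below it) and ceiling (gains clamp to
#'   it).  Must satisfy `energy_min < energy_init <= energy_max`.
#' @param heading initial heading in radians (default drawn by the engine).
#' @return a `dispersim_disperser` list.
#' @export
new_disperser <- function(id, sex, location, energy_init, energy_min,
                          energy_max, heading = 0) {
  sex <- match.arg(sex, c("male", "female"))
  if (!(energy_min < energy_init && energy_init <= energy_max)) {
    .stop_cfg("energy bounds must satisfy min < initial <= max")
  }
  structure(list(
    id = as.integer(id), sex = sex,
    energy = energy_init, energy_init = energy_init,
    energy_min = energy_min, energy_max = energy_max,
    loc = as.numeric(location), natal_origin = as.numeric(location),
    heading = heading,
    activity = "searching", vigilance = "risky",
    steps_taken = 0L, sites_visited = 0L,
    memory = new_memory(),
    status = "dispersing", cause = NA_character_,
    death_loc = NULL, death_step = NA_integer_,
    settled_step = NA_integer_, range = NULL,
    last_suit_feature = NA_integer_, bouts = NULL
  ), class = "dispersim_disperser")
}

# ---------------------------------------------------------------------------
# Memory map: an append-only, time-ordered record of perceived regions with
# the suitability/occupancy status they had when perceived.  The effective
# status at a point is that of the LATEST record covering it (latest wins).
# Stored in an environment so per-step appends do not copy the whole agent.

#' Create an empty memory map
#' @return a `dispersim_memory` environment.
#' @export
new_memory <- function() {
  m <- new.env(parent = emptyenv())
  m$n <- 0L
  m$regions <- vector("list", 64L)
  m$t <- numeric(64L)
  m$suit <- numeric(64L)
  m$occm <- numeric(64L)
  m$occf <- numeric(64L)
  m$area <- numeric(64L)
  m$bb1 <- numeric(64L); m$bb2 <- numeric(64L)
  m$bb3 <- numeric(64L); m$bb4 <- numeric(64L)
  class(m) <- "dispersim_memory"
  m
}

#' Record a perceived region in a memory map
#'
#' Appends a region with its perceived suitability/occupancy status.
#' Records must arrive in non-decreasing time order; re-perceiving an area
#' later simply appends a newer record, which wins at query time.
#'
#' @param memory a `dispersim_memory`.
#' @param region convex polygon matrix (a perception-corridor piece clipped
#'   to one suitability feature).
#' @param status list or vector with `suitable`, `occupied_male`,
#'   `occupied_female` flags (0/1).
#' @param t timestamp (simulation minutes).
#' @return the memory map, invisibly.
#' @export
remember <- function(memory, region, status, t) {
  n <- memory$n
  if (n > 0L && t < memory$t[n]) {
    stop(errorCondition("memory records must be appended in time order",
                        class = c("dispersim_internal_error", "error")))
  }
  if (n + 1L > length(memory$regions)) {    # grow by doubling
    cap <- 2L * length(memory$regions)
    memory$regions <- c(memory$regions, vector("list", cap - length(memory$regions)))
    length(memory$t) <- cap; length(memory$suit) <- cap
    length(memory$occm) <- cap; length(memory$occf) <- cap
    length(memory$area) <- cap
    length(memory$bb1) <- cap; length(memory$bb2) <- cap
    length(memory$bb3) <- cap; length(memory$bb4) <- cap
  }
  n <- n + 1L
  memory$n <- n
  memory$regions[[n]] <- region
  memory$t[n] <- t
  s <- as.list(status)
  memory$suit[n] <- as.numeric(s$suitable)
  memory$occm[n] <- as.numeric(s$occupied_male)
  memory$occf[n] <- as.numeric(s$occupied_female)
  memory$area[n] <- geom_area(region)
  bb <- geom_bbox(region)
  memory$bb1[n] <- bb[1]; memory$bb2[n] <- bb[2]
  memory$bb3[n] <- bb[3]; memory$bb4[n] <- bb[4]
  invisible(memory)
}

#' Index of the latest record covering a point (0 when none)
#' @noRd
memory_latest_index <- function(memory, p) {
  n <- memory$n
  if (n == 0L) return(0L)
  sel <- seq_len(n)
  hit <- which(p[1] >= memory$bb1[sel] & p[1] <= memory$bb3[sel] &
               p[2] >= memory$bb2[sel] & p[2] <= memory$bb4[sel])
  for (i in rev(hit)) {
    if (point_in_poly(p[1], p[2], memory$regions[[i]])) return(i)
  }
  0L
}

#' Effective remembered status at a point
#'
#' Scans records from newest to oldest and returns the status of the first
#' record whose region covers the point (latest wins), or `NULL` if the
#' point was never perceived.
#'
#' @param memory a `dispersim_memory`.
#' @param p numeric length-2 point.
#' @return list with `suitable`, `occupied_male`, `occupied_female`, `t`,
#'   or `NULL`.
#' @export
memory_status <- function(memory, p) {
  i <- memory_latest_index(memory, p)
  if (i == 0L) return(NULL)
  list(suitable = memory$suit[i], occupied_male = memory$occm[i],
       occupied_female = memory$occf[i], t = memory$t[i])
}

#' Sample candidate home-range points from memory
#'
#' Draws up to `n` points uniformly from the union of remembered regions
#' whose effective (latest-wins) status is suitable and not occupied by the
#' animal's own sex; an empty eligible union yields an empty result.
#'
#' Sampling proposes an eligible-status record with probability
#' proportional to its area, draws a uniform point inside it, and accepts
#' the point iff that record is the latest record covering it — which is
#' exactly the uniform distribution over the eligible latest-wins union,
#' but remains fast when the eligible area is a small part of the memory's
#' footprint.  Capped at 10000 proposals per point and 10 * n proposals
#' per call, so a hopeless draw (eligible records buried under newer
#' ineligible ones) costs bounded work and simply returns fewer points.
#'
#' @param memory a `dispersim_memory`.
#' @param sex the settling animal's sex (its own sex drives exclusion).
#' @param n maximum number of points.
#' @return matrix with columns x, y (possibly 0 rows).
#' @export
candidate_points <- function(memory, sex, n) {
  stopifnot(n >= 1)
  empty <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  if (memory$n == 0L) return(empty)
  idx <- seq_len(memory$n)
  occ <- if (identical(sex, "male")) memory$occm else memory$occf
  # re-perceiving a region appends an exact-region overwrite; only the
  # newest record per identical region (bbox + area key) can be the latest
  # anywhere inside it, so older duplicates are pruned from the proposal set
  key <- paste(memory$bb1[idx], memory$bb2[idx], memory$bb3[idx],
               memory$bb4[idx], memory$area[idx])
  newest <- !duplicated(key, fromLast = TRUE)
  elig <- idx[newest & memory$suit[idx] == 1 & occ[idx] == 0]
  if (!length(elig)) return(empty)
  areas <- memory$area[elig]
  if (sum(areas) <= 0) return(empty)
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  budget <- 10L * n
  for (k in seq_len(n)) {
    tries <- 0L
    while (tries < 10000L && budget > 0L) {
      tries <- tries + 1L
      budget <- budget - 1L
      r <- if (length(elig) == 1L) elig else
        elig[sample.int(length(elig), 1L, prob = areas)]
      reg <- memory$regions[[r]]
      p <- c(stats::runif(1, memory$bb1[r], memory$bb3[r]),
             stats::runif(1, memory$bb2[r], memory$bb4[r]))
      if (!point_in_poly(p[1], p[2], reg)) next
      if (memory_latest_index(memory, p) == r) {
        got <- got + 1L
        pts[got, ] <- p
        break
      }
    }
    if (budget <= 0L) break
  }
  out <- pts[seq_len(got), , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}

# ---------------------------------------------------------------------------

#' Initialise the population under one of three scenarios
#'
#' `release_only` creates dispersers at the landscape's release points (a
#' reintroduction); `residents_only` places established residents from a
#' roster of home-range centres, so the first dispersers arise from
#' breeding; `combined` does both (population augmentation).
#'
#' @param land a `dispersim_landscape`.
#' @param scenario `"release_only"`, `"residents_only"` or `"combined"`.
#' @param cfg a `sim_config()`; supplies energy bounds, minimum home-range
#'   areas, and (for resident scenarios) `residents`, a data frame of
#'   `x`, `y`, `sex` home-range centres.
#' @return list with `residents` (each carrying a generated home range) and
#'   `dispersers`.
#' @export
initialize_population <- function(land, scenario, cfg) {
  scenario <- match.arg(scenario, c("release_only", "residents_only", "combined"))
  residents <- list()
  dispersers <- list()
  want_release <- scenario %in% c("release_only", "combined")
  want_residents <- scenario %in% c("residents_only", "combined")

  if (want_residents) {
    roster <- cfg$residents
    if (scenario == "residents_only" && (is.null(roster) || !nrow(roster))) {
      .stop_cfg("scenario '", scenario, "' requires a resident roster (x, y, sex)")
    }
    if (!is.null(roster) && nrow(roster)) {
      roster <- as.data.frame(roster)
      for (i in seq_len(nrow(roster))) {
        sex <- match.arg(roster$sex[i], c("male", "female"))
        center <- c(roster$x[i], roster$y[i])
        a_min <- cfg$hr_min_area[[sex]]
        poly <- NULL
        for (try in 1:100) {
          cand <- generate_polygon(center, a_min)
          ok <- TRUE
          for (r in residents) {
            if (identical(r$sex, sex) &&
                range_overlap_area(cand, r$range$poly) > 1e-6) { ok <- FALSE; break }
          }
          if (ok) { poly <- cand; break }
        }
        if (is.null(poly)) {
          .stop_cfg("could not place resident ", i,
                    " without same-sex home-range overlap; spread the roster out")
        }
        residents[[length(residents) + 1L]] <- list(
          id = length(residents) + 1L, sex = sex,
          range = list(center = center, poly = poly, owner = length(residents) + 1L,
                       sex = sex, established_at = 0)
        )
      }
    }
  }

  if (want_release) {
    rel <- land$release
    if (scenario == "release_only" && (is.null(rel) || !nrow(rel))) {
      .stop_cfg("scenario 'release_only' requires a non-empty release layer")
    }
    if (!is.null(rel) && nrow(rel)) {
      nxt_sex <- "male"
      for (i in seq_len(nrow(rel))) {
        cnt <- as.integer(rel$count[i])
        for (k in seq_len(cnt)) {
          sex <- if (!is.null(rel$sex) && !is.na(rel$sex[i])) {
            match.arg(rel$sex[i], c("male", "female"))
          } else {
            s <- nxt_sex
            nxt_sex <- if (nxt_sex == "male") "female" else "male"
            s
          }
          dispersers[[length(dispersers) + 1L]] <- new_disperser(
            id = length(dispersers) + 1L, sex = sex,
            location = c(rel$x[i], rel$y[i]),
            energy_init = cfg$energy_init, energy_min = cfg$energy_min,
            energy_max = cfg$energy_max
          )
        }
      }
    }
  }

  if (!length(residents) && !length(dispersers)) {
    .stop_cfg("scenario '", scenario, "' produced an empty population ",
              "(no residents and no releases)")
  }
  list(residents = residents, dispersers = dispersers)
}
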