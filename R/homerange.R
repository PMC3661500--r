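# Home-range establishment: the settlement trigger, candidate scoring under
# the four selection criteria, range-polygon generation, and settlement with
# same-sex exclusion.

#' Has the settlement trigger been reached?
#'
#' Animals begin choosing home-range centres once either a set number of
#' active time-steps have elapsed since dispersal began (`"steps"` mode) or
#' they have visited a set number of distinct suitability polygons that
#' were suitable and unoccupied by their own sex at entry (`"sites"` mode).
#'
#' @param animal a `dispersim_disperser`.
#' @param mode `"steps"` or `"sites"`.
#' @param threshold integer >= 1.
#' @return logical.
#' @export
trigger_reached <- function(animal, mode, threshold) {
  stopifnot(threshold >= 1)
  mode <- match.arg(mode, c("steps", "sites"))
  if (mode == "steps") animal$steps_taken >= threshold
  else animal$sites_visited >= threshold
}

#' Choose a home-range centre among candidate sites
#'
#' Each candidate gets weight `W = Q * exp(-d / w)` where `d` is its
#' distance from the animal and `Q` depends on the selection criterion:
#' 1 for `"closest"`, food quality (expected gain, normalised by the
#' candidate-set maximum) for `"food"`, safety (`1 - p_mortality`,
#' normalised) for `"risk"`, and their product for `"integrated"`.  The
#' site is then sampled with probability proportional to `W`, so selection
#' is weighted toward high-quality, nearby sites but remains stochastic;
#' a very large distance-weighting factor `w` makes proximity irrelevant.
#'
#' @param candidates data frame with columns `x`, `y`, `dist`,
#'   `food_quality`, `risk_quality`.
#' @param criterion one of `"closest"`, `"food"`, `"risk"`, `"integrated"`.
#' @param w distance weighting factor (> 0, metres).
#' @return the chosen row (one-row data frame), or `NULL` when the
#'   candidate set is empty (the animal keeps dispersing).
#' @export
score_candidates <- function(candidates, criterion, w) {
  criterion <- match.arg(criterion, c("closest", "food", "risk", "integrated"))
  stopifnot(w > 0)
  if (is.null(candidates) || !nrow(candidates)) return(NULL)
  q <- rep(1, nrow(candidates))
  norm <- function(v) if (max(v) > 0) v / max(v) else rep(1, length(v))
  if (criterion %in% c("food", "integrated")) q <- q * norm(candidates$food_quality)
  if (criterion %in% c("risk", "integrated")) q <- q * norm(candidates$risk_quality)
  wts <- q * exp(-candidates$dist / w)
  if (sum(wts) <= 0) wts <- rep(1, length(wts))
  i <- sample.int(nrow(candidates), 1L, prob = wts)
  candidates[i, , drop = FALSE]
}

#' Generate a home-range polygon around a centre
#'
#' Twelve vertices at equally spaced angles (with one uniformly random
#' rotation) and radii drawn Normal(r0, 0.15 r0) truncated positive, where
#' r0 makes the regular 12-gon attain exactly the minimum area `a_min`.
#' Vertices sorted by angle around the centre make the ring star-shaped and
#' therefore simple.  Regenerated (up to 100 draws) until the area reaches
#' `a_min`.
#'
#' @param center numeric length-2 centre point.
#' @param a_min minimum home-range area in square metres (> 0).
#' @param radius_cv coefficient of variation of the vertex radii (default
#'   0.15; 0 gives the exact regular 12-gon of area `a_min`).
#' @return polygon matrix with area >= `a_min`.
#' @export
generate_polygon <- function(center, a_min, radius_cv = 0.15) {
  stopifnot(a_min > 0, radius_cv >= 0)
  k <- 12L
  r0 <- sqrt(2 * a_min / (k * sin(2 * pi / k)))
  for (try in 1:100) {
    th <- sort(stats::runif(1, 0, 2 * pi / k) + (0:(k - 1)) * 2 * pi / k)
    r <- if (radius_cv > 0) stats::rnorm(k, r0, radius_cv * r0) else rep(r0, k)
    bad <- which(r <= 0)
    while (length(bad)) {                 # truncation: redraw non-positive radii
      r[bad] <- stats::rnorm(length(bad), r0, radius_cv * r0)
      bad <- which(r <= 0)
    }
    xy <- cbind(center[1] + r * cos(th), center[2] + r * sin(th),
                deparse.level = 0)
    if (geom_area(xy) >= a_min * (1 - 1e-12)) return(xy)
  }
  stop(errorCondition("home-range polygon generation failed after 100 draws",
                      class = c("dispersim_generation_error", "error")))
}

#' Overlap area between two home-range polygons
#'
#' @param poly_a,poly_b polygon matrices (star-shaped, as generated).
#' @return intersection area in square metres.
#' @export
range_overlap_area <- function(poly_a, poly_b) {
  ba <- geom_bbox(poly_a); bb <- geom_bbox(poly_b)
  if (ba[1] > bb[3] || ba[3] < bb[1] || ba[2] > bb[4] || ba[4] < bb[2]) return(0)
  a <- 0
  for (pc in region_pieces(poly_b)) a <- a + intersection_area(poly_a, pc)
  a
}

#' Mark a home range's occupancy on a suitability map
#'
#' Every suitability feature the range polygon overlaps (by more than a
#' square-metre sliver) gains the owner sex's occupancy flag; `value = 0`
#' clears the flags when a range is freed by a death.  Feature-level flags
#' mirror the coarse occupancy semantics of the suitability layer; the live
#' range registry remains the authoritative record for exact exclusion.
#'
#' @param map suitability `dispersim_map`.
#' @param range_poly polygon matrix.
#' @param sex `"male"` or `"female"`.
#' @param value 1 to set, 0 to clear.
#' @return the updated map.
#' @export
apply_occupancy <- function(map, range_poly, sex, value = 1) {
  field <- if (identical(sex, "male")) "occupied_male" else "occupied_female"
  rb <- geom_bbox(range_poly)
  b <- map$bboxes
  cand <- which(b[, 1] <= rb[3] & b[, 3] >= rb[1] &
                b[, 2] <= rb[4] & b[, 4] >= rb[2])
  pieces <- region_pieces(range_poly)
  for (i in cand) {
    a <- 0
    for (pc in pieces) a <- a + intersection_area(map$polys[[i]], pc)
    if (a > 1e-6) map$attrs[[field]][i] <- value
  }
  map
}

#' Usable area of a region for one sex
#'
#' Area of the region lying in suitability features that are suitable and
#' not flagged as occupied by the given sex.
#'
#' @param map suitability `dispersim_map`.
#' @param region polygon matrix or list of polygons.
#' @param sex `"male"` or `"female"`.
#' @return area in square metres.
#' @export
usable_area <- function(map, region, sex) {
  field <- if (identical(sex, "male")) "occupied_male" else "occupied_female"
  pieces <- region_pieces(region)
  rb <- sapply(pieces, geom_bbox)
  rbb <- c(min(rb[1, ]), min(rb[2, ]), max(rb[3, ]), max(rb[4, ]))
  b <- map$bboxes
  cand <- which(b[, 1] <= rbb[3] & b[, 3] >= rbb[1] &
                b[, 2] <= rbb[4] & b[, 4] >= rbb[2])
  tot <- 0
  for (i in cand) {
    if (map$attrs$suitable[i] != 1 || map$attrs[[field]][i] != 0) next
    for (pc in pieces) tot <- tot + intersection_area(map$polys[[i]], pc)
  }
  tot
}

#' Attempt to establish a home range at a chosen site
#'
#' A candidate polygon is generated at the site.  Settlement succeeds iff
#' the polygon's overlap with every existing same-sex range is zero (within
#' 1e-6 m2) and its suitable, same-sex-unoccupied area reaches the sex's
#' minimum home-range area.  On success the animal settles (it becomes a
#' resident; occupancy flags are set by the engine); on failure the
#' rejected site (a small disc around the chosen centre) is remembered as
#' ineligible so later candidate draws avoid it, and the animal resumes
#' dispersal.
#'
#' @param animal a `dispersim_disperser`, already relocated to the site.
#' @param site one-row candidate (columns `x`, `y`) from
#'   [score_candidates()].
#' @param suit_map the active suitability map.
#' @param same_sex_ranges list of existing same-sex range polygons.
#' @param a_min the sex's minimum home-range area.
#' @param t timestamp for bookkeeping (memory record, establishment time).
#' @return list with `settled` (logical), `animal` (updated), and on
#'   success `range` (centre, polygon, sex).
#' @export
attempt_settlement <- function(animal, site, suit_map, same_sex_ranges,
                               a_min, t) {
  center <- c(site$x[1], site$y[1])
  poly <- generate_polygon(center, a_min)
  overlap <- 0
  for (rp in same_sex_ranges) {
    overlap <- overlap + range_overlap_area(poly, rp)
    if (overlap > 1e-6) break
  }
  ok <- overlap <= 1e-6
  if (ok) {
    usable <- usable_area(suit_map, poly, animal$sex)
    ok <- usable >= a_min
  }
  if (!ok) {
    # mark the rejected SITE ineligible: a small disc around the chosen
    # centre (a quarter of the nominal range radius), so the same spot is
    # not immediately re-drawn while the surrounding patch stays eligible
    r0 <- sqrt(2 * a_min / (12 * sin(2 * pi / 12)))
    remember(animal$memory, disc_poly(center, 0.25 * r0, 16L),
             list(suitable = 0, occupied_male = 0, occupied_female = 0), t)
    return(list(settled = FALSE, animal = animal))
  }
  animal$status <- "settled"
  animal$range <- list(center = center, poly = poly, owner = animal$id,
                       sex = animal$sex, established_at = t)
  list(settled = TRUE, animal = animal, range = animal$range)
}

#' Kill animals still dispersing at season close
#'
#' Any animal that has not settled by the last time-step of the dispersal
#' season dies with cause `"season_end"`.
#'
#' @param animals list of dispersers.
#' @return the updated list.
#' @export
end_of_season <- function(animals) {
  lapply(animals, function(a) {
    if (identical(a$status, "dispersing")) {
      a$status <- "dead"
      a$cause <- "season_end"
      a$death_loc <- a$loc
    }
    a
  })
}
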