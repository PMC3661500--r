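# Per-step movement: correlated-random-walk draws, habitat-boundary
# crossing decisions, path construction with specular reflection at the map
# extent, and the perceptual window around the realised path.

#' Wrap an angle to (-pi, pi]
#' @noRd
wrap_angle <- function(a) {
  if (a > -pi && a <= pi) return(a)   # already in range: keep exact
  w <- ((a + pi) %% (2 * pi)) - pi
  if (w <= -pi) w + 2 * pi else w
}

#' Draw the next heading of a correlated random walk
#'
#' The turning angle is wrapped Cauchy with centre 0 and concentration
#' `rho` (the mean resultant length): `rho = 0` gives uniform turning (pure
#' random walk), `rho = 1` gives no turning (straight-line movement).
#' Sampling uses the exact inverse-CDF transform.
#'
#' @param prev_heading previous heading in radians.
#' @param rho concentration in \[0, 1\].
#' @return new heading in (-pi, pi].
#' @export
sample_turn_angle <- function(prev_heading, rho) {
  stopifnot(rho >= 0, rho <= 1)
  if (rho >= 1) return(wrap_angle(prev_heading))
  u <- stats::runif(1)
  theta <- if (rho <= 0) {
    2 * pi * u - pi
  } else {
    2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5)))
  }
  wrap_angle(prev_heading + theta)
}

#' Draw a step length
#'
#' Normal with the polygon's mean and standard deviation, truncated below
#' at zero by clamping (negative draws become 0).
#'
#' @param mean,sd metres per time-step, both >= 0.
#' @return step length in metres.
#' @export
sample_step_length <- function(mean, sd) {
  stopifnot(mean >= 0, sd >= 0)
  if (sd <= 0) return(mean)
  max(stats::rnorm(1, mean, sd), 0)
}

#' Decide whether to cross a habitat boundary
#'
#' The animal compares the permeability ranks of the polygon it is in
#' (`q_from`) and the polygon it would enter (`q_to`) to a uniform draw:
#' it crosses iff the draw is below `q_to / (q_from + q_to)`.  A rank-0
#' destination is impassable (never entered); a rank-0 origin is always
#' left.  Equal ranks cross half the time.
#'
#' @param q_from,q_to crossing ranks, both >= 0 and not both 0.
#' @return logical: cross the boundary?
#' @export
crossing_decision <- function(q_from, q_to) {
  stopifnot(q_from >= 0, q_to >= 0)
  if (q_from == 0 && q_to == 0) {
    stop(errorCondition("both crossing ranks are 0: animal in impassable habitat",
                        class = c("dispersim_state_error", "error")))
  }
  stats::runif(1) < q_to / (q_from + q_to)
}

#' Advance an animal one time-step across the movement map
#'
#' Draws a heading (wrapped-Cauchy turn at the origin polygon's tortuosity)
#' and a step length, then traverses the ray.  At each polygon boundary a
#' crossing decision is made from the two polygons' permeability ranks; a
#' refusal truncates the step at the boundary and forfeits the remaining
#' distance.  At the map extent the heading reflects specularly and the
#' traversal continues, so animals always stay in-domain.  Tortuosity,
#' step length and the crossing rank of the current polygon are taken from
#' the polygon containing the step's origin (via `eff`).
#'
#' @param loc numeric length-2 current location.
#' @param heading previous heading (radians).
#' @param map the active movement `dispersim_map`.
#' @param eff effective parameters from [resolve_params()].
#' @return a `dispersim_path` list: `origin`, `terminus`, `heading_out`,
#'   `truncated_by_boundary`, `waypoints` (boundary points crossed),
#'   `pieces` (list of straight sub-segments, split at reflections),
#'   `decisions` (one record per boundary decision: from/to feature ids and
#'   whether the animal crossed), `length_drawn`, `length_realized`.
#' @export
advance <- function(loc, heading, map, eff) {
  h <- sample_turn_angle(heading, eff$tortuosity)
  len <- sample_step_length(eff$step_mean, eff$step_sd)
  dir <- c(cos(h), sin(h))
  pos <- loc
  rem <- len
  scale <- max(map$extent[3] - map$extent[1], map$extent[4] - map$extent[2])
  probe_eps <- 1e-9 * scale
  if (is.na(locate_feature(map, pos))) {
    stop(errorCondition("animal location outside map extent",
                        class = c("dispersim_bounds_error", "error")))
  }
  truncated <- FALSE
  waypoints <- list()
  decisions <- list()
  pieces <- list()
  piece_start <- pos
  realized <- 0
  iter <- 0L
  while (rem > probe_eps && (iter <- iter + 1L) < 1000L) {
    # anchor the traversal feature by probing slightly ahead of the ray, so
    # a position lying exactly on a shared edge resolves to the side the
    # ray actually travels through
    probe0 <- pos + probe_eps * dir
    out_x <- probe0[1] < map$extent[1] || probe0[1] > map$extent[3]
    out_y <- probe0[2] < map$extent[2] || probe0[2] > map$extent[4]
    if (out_x || out_y) {           # on the extent edge heading out: reflect
      pieces[[length(pieces) + 1L]] <- list(p0 = piece_start, p1 = pos)
      if (out_x) dir[1] <- -dir[1]
      if (out_y) dir[2] <- -dir[2]
      piece_start <- pos
      next
    }
    cur0 <- locate_feature(map, pos, strict = TRUE)
    cur1 <- locate_feature(map, probe0, strict = TRUE)
    if (!is.na(cur0) && !is.na(cur1) && cur0 != cur1) {
      # a boundary lies within the probe distance ahead (e.g. the animal
      # was left just inside an edge by an earlier refusal): decide the
      # crossing here rather than letting the probe jump the edge
      q_from <- map$attrs$crossing[cur0]
      q_to <- map$attrs$crossing[cur1]
      crossed <- crossing_decision(q_from, q_to)
      decisions[[length(decisions) + 1L]] <- c(from = cur0, to = cur1,
                                               crossed = as.integer(crossed))
      if (!crossed) {
        truncated <- TRUE
        rem <- 0
        break
      }
      waypoints[[length(waypoints) + 1L]] <- pos
      cur <- cur1
    } else {
      cur <- if (!is.na(cur1)) cur1 else cur0
    }
    if (is.na(cur)) {               # numerical sliver: inch forward
      pos <- probe0
      rem <- rem - probe_eps
      next
    }
    exit <- ray_exit(pos, dir, rem, map$polys[[cur]])
    if (is.null(exit)) {            # step ends inside the current polygon
      pos <- pos + rem * dir
      realized <- realized + rem
      rem <- 0
      break
    }
    xpt <- pos + exit$t * dir
    probe <- xpt + probe_eps * dir
    pout_x <- probe[1] < map$extent[1] || probe[1] > map$extent[3]
    pout_y <- probe[2] < map$extent[2] || probe[2] > map$extent[4]
    if (pout_x || pout_y) {         # specular reflection at the extent
      realized <- realized + exit$t
      rem <- rem - exit$t
      pieces[[length(pieces) + 1L]] <- list(p0 = piece_start, p1 = xpt)
      if (pout_x) dir[1] <- -dir[1]
      if (pout_y) dir[2] <- -dir[2]
      pos <- xpt
      piece_start <- pos
      next
    }
    nb <- locate_feature(map, probe, strict = TRUE)
    if (is.na(nb) || nb == cur) {   # grazed a vertex: inch past it
      realized <- realized + exit$t
      rem <- rem - exit$t - probe_eps
      pos <- probe
      next
    }
    q_from <- map$attrs$crossing[cur]
    q_to <- map$attrs$crossing[nb]
    crossed <- crossing_decision(q_from, q_to)
    decisions[[length(decisions) + 1L]] <- c(from = cur, to = nb,
                                             crossed = as.integer(crossed))
    if (crossed) {
      waypoints[[length(waypoints) + 1L]] <- xpt
      realized <- realized + exit$t
      rem <- rem - exit$t
      pos <- xpt                    # next iteration re-anchors into nb
    } else {                        # refused: truncate at the boundary
      realized <- realized + exit$t
      pos <- xpt - probe_eps * dir  # rest just inside the origin-side polygon
      truncated <- TRUE
      rem <- 0
      break
    }
  }
  pieces[[length(pieces) + 1L]] <- list(p0 = piece_start, p1 = pos)
  structure(list(origin = loc, terminus = pos,
                 heading_out = wrap_angle(atan2(dir[2], dir[1])),
                 truncated_by_boundary = truncated,
                 waypoints = waypoints, pieces = pieces,
                 decisions = decisions,
                 length_drawn = len, length_realized = realized),
            class = "dispersim_path")
}

#' Perceptual window around a movement path
#'
#' Buffers the realised path by the perception radius with round caps and
#' joins (a stadium per straight sub-segment).  This corridor is what the
#' animal senses during the step: the suitability and occupancy inside it
#' enter the memory map.
#'
#' @param segment a `dispersim_path` from [advance()], or a list with
#'   `pieces`.
#' @param radius perception radius in metres; 0 gives an empty region.
#' @return list of convex polygons (possibly empty) forming the corridor.
#' @export
perception_polygon <- function(segment, radius) {
  stopifnot(radius >= 0)
  if (radius <= 0) return(list())
  out <- list()
  for (pc in segment$pieces) {
    s <- stadium_poly(pc$p0, pc$p1, radius)
    if (!is.null(s)) out[[length(out) + 1L]] <- s
  }
  out
}
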