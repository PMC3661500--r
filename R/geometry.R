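# Planar computational-geometry primitives used throughout the package.
#
# A polygon is a numeric matrix with columns (x, y), vertices in ring order,
# last vertex NOT repeated.  All coordinates are planar map units (metres);
# no geographic CRS math is ever performed.  A "region" is a list of convex
# polygon pieces that are assumed mutually non-overlapping; unions of pieces
# are the only non-convex shapes the package ever clips with.

.geom_eps <- 1e-9

#' Signed area of a polygon ring (shoelace formula)
#' @param xy two-column coordinate matrix, ring order, not closed.
#' @return signed area; positive for counter-clockwise rings.
#' @noRd
geom_signed_area <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Absolute polygon area
#' @noRd
geom_area <- function(xy) abs(geom_signed_area(xy))

#' Force counter-clockwise vertex order
#' @noRd
geom_ccw <- function(xy) {
  if (geom_signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

#' Polygon vertex-ring centroid (area-weighted)
#' @noRd
geom_centroid <- function(xy) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < .geom_eps) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

#' Bounding box of a coordinate matrix
#' @return c(xmin, ymin, xmax, ymax)
#' @noRd
geom_bbox <- function(xy) {
  c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))
}

#' Boundary-inclusive point-in-polygon test, vectorised over points
#'
#' Even-odd ray casting; points lying on an edge (within a small tolerance
#' scaled to the polygon extent) count as inside, so that containment queries
#' on shared edges of a tessellation can be tie-broken by feature id.
#' @param px,py point coordinates (equal-length vectors)
#' @param xy polygon matrix
#' @param boundary when `TRUE` (default) points on an edge count as inside
#'   (needed for the min-id tie-break on shared edges); when `FALSE` the
#'   bare even-odd rule is used, which assigns edge-adjacent points to a
#'   single well-defined side.
#' @return logical vector
#' @noRd
point_in_poly <- function(px, py, xy, boundary = TRUE) {
  n <- nrow(xy)
  x <- xy[, 1]; y <- xy[, 2]
  xp <- c(x[n], x[-n]); yp <- c(y[n], y[-n])     # previous vertex per edge
  if (length(px) == 1L) {
    # scalar fast path, vectorised over edges (the dominant query shape)
    cond <- (y > py) != (yp > py)
    inside <- FALSE
    if (any(cond)) {
      xint <- x[cond] + (xp[cond] - x[cond]) * (py - y[cond]) /
        (yp[cond] - y[cond])
      inside <- (sum(px < xint) %% 2L) == 1L
    }
    if (!boundary) return(inside)
    if (inside) return(TRUE)
    eps <- 1e-9 * max(max(x) - min(x), max(y) - min(y), 1)
    cr <- (xp - x) * (py - y) - (yp - y) * (px - x)
    on <- abs(cr) <= eps * pmax(abs(xp - x) + abs(yp - y), 1) &
      px >= pmin(x, xp) - eps & px <= pmax(x, xp) + eps &
      py >= pmin(y, yp) - eps & py <= pmax(y, yp) + eps
    return(any(on))
  }
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  if (boundary) {
    scale <- max(max(x) - min(x), max(y) - min(y), 1)
    eps <- 1e-9 * scale
  }
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- xp[i]; yj <- yp[i]
    if (boundary) {
      # on-edge check: zero cross product and within edge bbox
      cr <- (xj - xi) * (py - yi) - (yj - yi) * (px - xi)
      on <- abs(cr) <= eps * max(abs(xj - xi) + abs(yj - yi), 1) &
        px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
        py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
      onedge <- onedge | on
    }
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside | onedge
}

#' Clip a polygon by the half-plane dot(normal, p - origin) <= 0
#' @noRd
clip_halfplane <- function(xy, origin, normal) {
  if (is.null(xy) || nrow(xy) < 3) return(NULL)
  n <- nrow(xy)
  d <- (xy[, 1] - origin[1]) * normal[1] + (xy[, 2] - origin[2]) * normal[2]
  scale <- max(abs(d), 1)
  keep <- d <= .geom_eps * scale
  if (all(keep)) return(xy)
  if (!any(keep)) return(NULL)
  outx <- numeric(0); outy <- numeric(0)
  j <- n
  for (i in seq_len(n)) {
    if (keep[i]) {
      if (!keep[j]) {                    # entering: add intersection
        t <- d[j] / (d[j] - d[i])
        outx <- c(outx, xy[j, 1] + t * (xy[i, 1] - xy[j, 1]))
        outy <- c(outy, xy[j, 2] + t * (xy[i, 2] - xy[j, 2]))
      }
      outx <- c(outx, xy[i, 1]); outy <- c(outy, xy[i, 2])
    } else if (keep[j]) {                # leaving: add intersection
      t <- d[j] / (d[j] - d[i])
      outx <- c(outx, xy[j, 1] + t * (xy[i, 1] - xy[j, 1]))
      outy <- c(outy, xy[j, 2] + t * (xy[i, 2] - xy[j, 2]))
    }
    j <- i
  }
  if (length(outx) < 3) return(NULL)
  cbind(outx, outy, deparse.level = 0)
}

#' Sutherland-Hodgman clip of an arbitrary simple polygon against a CONVEX clip
#' @param subject polygon matrix (any simple polygon)
#' @param clip convex polygon matrix
#' @return clipped polygon matrix or NULL if empty
#' @noRd
clip_convex <- function(subject, clip) {
  clip <- geom_ccw(clip)
  out <- subject
  n <- nrow(clip)
  j <- n
  for (i in seq_len(n)) {
    a <- clip[j, ]; b <- clip[i, ]
    # inside = left of edge a->b; half-plane normal points right of edge
    normal <- c(b[2] - a[2], -(b[1] - a[1]))
    out <- clip_halfplane(out, a, normal)
    if (is.null(out)) return(NULL)
    j <- i
  }
  if (geom_area(out) < .geom_eps) return(NULL)
  out
}

#' Area of the intersection of a simple polygon with a convex polygon
#' @noRd
intersection_area <- function(subject, clip) {
  # quick bbox reject
  bs <- geom_bbox(subject); bc <- geom_bbox(clip)
  if (bs[1] > bc[3] || bs[3] < bc[1] || bs[2] > bc[4] || bs[4] < bc[2]) return(0)
  out <- clip_convex(subject, clip)
  if (is.null(out)) 0 else geom_area(out)
}

#' Is the polygon convex (collinear runs allowed)?
#' @noRd
geom_is_convex <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(TRUE)
  x <- xy[, 1]; y <- xy[, 2]
  i1 <- seq_len(n); i2 <- c(2:n, 1L); i3 <- c(3:n, 1L, 2L)
  cr <- (x[i2] - x[i1]) * (y[i3] - y[i2]) - (y[i2] - y[i1]) * (x[i3] - x[i2])
  scale <- max(abs(cr), 1)
  all(cr >= -.geom_eps * scale) || all(cr <= .geom_eps * scale)
}

#' Decompose a polygon into convex pieces by fanning from an interior point
#'
#' Exact for polygons that are star-shaped with respect to their centroid
#' (every polygon this package generates is, by construction); validated by
#' comparing the summed triangle area to the ring area.
#' @return list of triangle matrices
#' @noRd
fan_pieces <- function(xy) {
  xy <- geom_ccw(xy)
  if (geom_is_convex(xy)) return(list(xy))
  c0 <- geom_centroid(xy)
  n <- nrow(xy)
  pieces <- vector("list", n)
  tot <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    tri <- rbind(c0, xy[i, ], xy[j, ])
    pieces[[i]] <- tri
    tot <- tot + geom_area(tri)
  }
  a <- geom_area(xy)
  if (abs(tot - a) > 1e-6 * max(a, 1)) {
    stop("polygon is not star-shaped with respect to its centroid; ",
         "cannot decompose into convex pieces", call. = FALSE)
  }
  pieces
}

#' Convert a polygon or list of polygons into a list of convex pieces
#' @noRd
region_pieces <- function(x) {
  if (is.matrix(x)) return(fan_pieces(x))
  if (is.list(x)) return(unlist(lapply(x, fan_pieces), recursive = FALSE))
  stop("cannot interpret region", call. = FALSE)
}

#' Discretised disc polygon
#' @noRd
disc_poly <- function(center, r, n = 48L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th), deparse.level = 0)
}

#' Stadium (capsule) polygon: a segment buffered by radius r with round caps
#'
#' Degenerate segments (length ~ 0) buffer to a disc.
#' @noRd
stadium_poly <- function(p0, p1, r, n_arc = 24L) {
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (r <= 0) return(NULL)
  if (len < .geom_eps) return(disc_poly(p0, r, 2L * n_arc))
  ang <- atan2(d[2], d[1])
  th1 <- ang + pi / 2 + seq(0, pi, length.out = n_arc)   # cap around p0
  th2 <- ang - pi / 2 + seq(0, pi, length.out = n_arc)   # cap around p1
  xy <- rbind(
    cbind(p1[1] + r * cos(th2), p1[2] + r * sin(th2)),
    cbind(p0[1] + r * cos(th1), p0[2] + r * sin(th1))
  )
  geom_ccw(xy)
}

#' First exit of a ray from a polygon
#'
#' Finds the smallest t in (tol, max_t] at which pos + t * dir crosses an
#' edge of the polygon.
#' @return list(t=, edge=) or NULL when the ray stays inside up to max_t
#' @noRd
ray_exit <- function(pos, dir, max_t, xy) {
  n <- nrow(xy)
  ax <- xy[, 1]; ay <- xy[, 2]
  j <- c(2:n, 1L)
  ex <- ax[j] - ax; ey <- ay[j] - ay
  denom <- dir[1] * ey - dir[2] * ex
  wx <- ax - pos[1]; wy <- ay - pos[2]
  ok <- abs(denom) > .geom_eps
  t <- (wx * ey - wy * ex) / denom
  s <- (wx * dir[2] - wy * dir[1]) / denom
  # exclude only the t = 0 self-intersection at the entry edge: the cutoff
  # scales with the polygon size (floating error of the intersection), NOT
  # with the step length, or nearby boundaries ahead of a nudged position
  # would be skipped
  tol <- 1e-12 * max(max(ax) - min(ax), max(ay) - min(ay), 1)
  valid <- ok & s >= -1e-12 & s <= 1 + 1e-12 & t > tol & t <= max_t
  if (!any(valid)) return(NULL)
  k <- which(valid)[which.min(t[valid])]
  list(t = t[k], edge = k)
}

#' Voronoi tessellation of a rectangle, by half-plane clipping
#'
#' O(n^2) construction: each site's cell is the extent rectangle clipped by
#' the bisector half-plane against every other site. Exact and convex, which
#' is all the synthetic-landscape generator needs at its patch counts.
#' @param sites n x 2 matrix of generator points
#' @param extent c(xmin, ymin, xmax, ymax)
#' @return list of convex polygon matrices, one per site
#' @noRd
voronoi_cells <- function(sites, extent) {
  rect <- cbind(extent[c(1, 3, 3, 1)], extent[c(2, 2, 4, 4)])
  n <- nrow(sites)
  lapply(seq_len(n), function(i) {
    cell <- rect
    for (jj in seq_len(n)) {
      if (jj == i || is.null(cell)) next
      m <- (sites[i, ] + sites[jj, ]) / 2
      cell <- clip_halfplane(cell, m, sites[jj, ] - sites[i, ])
    }
    if (is.null(cell)) stop("degenerate Voronoi cell (duplicate sites?)",
                            call. = FALSE)
    cell
  })
}
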