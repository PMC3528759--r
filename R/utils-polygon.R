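# Planar polygon primitives shared by the geometry, MRI-simulation and solver
# modules. Polygons are n x 2 matrices of vertices in mm, implicitly closed
# (last vertex connects back to the first), stored counter-clockwise.

#' Signed area of a closed polygon (shoelace formula)
#'
#' Positive for counter-clockwise vertex order.
#'
#' @param xy n x 2 numeric matrix of vertices (closed implicitly).
#' @return Signed area in the square of the vertex units.
#' @export
polygon_signed_area <- function(xy) {
  xy <- as_polygon(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  sum(x * ys - xs * y) / 2
}

#' Absolute polygon area
#' @inheritParams polygon_signed_area
#' @return Area (>= 0).
#' @export
polygon_area <- function(xy) abs(polygon_signed_area(xy))

#' Polygon perimeter
#' @inheritParams polygon_signed_area
#' @export
polygon_perimeter <- function(xy) {
  xy <- as_polygon(xy)
  d <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE]) - xy
  sum(sqrt(rowSums(d^2)))
}

as_polygon <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || nrow(xy) < 3L || !is.numeric(xy) || anyNA(xy) ||
      any(!is.finite(xy))) {
    stop("polygon must be a finite numeric n x 2 matrix with n >= 3")
  }
  # drop duplicated closing vertex if present
  if (isTRUE(all.equal(xy[1L, ], xy[nrow(xy), ], check.attributes = FALSE))) {
    xy <- xy[-nrow(xy), , drop = FALSE]
  }
  xy
}

ensure_ccw <- function(xy) {
  xy <- as_polygon(xy)
  if (polygon_signed_area(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

polygon_centroid <- function(xy) {
  xy <- as_polygon(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(xy))
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

# segment (p1,p2) x (p3,p4) proper/improper intersection test
segments_intersect <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  if (((d1 > eps & d2 < -eps) | (d1 < -eps & d2 > eps)) &&
      ((d3 > eps & d4 < -eps) | (d3 < -eps & d4 > eps))) return(TRUE)
  FALSE
}

cross2 <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]

#' Test that a closed polygon is simple (non-self-intersecting)
#'
#' Brute-force pairwise edge check; adequate for the contour sizes used here
#' (tens of vertices).
#'
#' @inheritParams polygon_signed_area
#' @return Logical.
#' @export
polygon_is_simple <- function(xy) {
  xy <- as_polygon(xy)
  n <- nrow(xy)
  nxt <- c(seq_len(n)[-1L], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (sharing a vertex)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      if (segments_intersect(xy[i, ], xy[nxt[i], ], xy[j, ], xy[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Point-in-polygon test
#'
#' @param px,py Coordinates of query points.
#' @inheritParams polygon_signed_area
#' @return Logical vector.
#' @export
points_in_polygon <- function(px, py, xy) {
  xy <- as_polygon(xy)
  pracma::inpolygon(px, py, xy[, 1L], xy[, 2L])
}

#' Unsigned distance from points to a polygon boundary
#'
#' Minimum Euclidean distance from each query point to the closed polyline.
#'
#' @inheritParams points_in_polygon
#' @return Numeric vector of distances (>= 0).
#' @export
dist_to_polygon <- function(px, py, xy) {
  xy <- as_polygon(xy)
  n <- nrow(xy)
  ax <- xy[, 1L]; ay <- xy[, 2L]
  bx <- c(ax[-1L], ax[1L]); by <- c(ay[-1L], ay[1L])
  ex <- bx - ax; ey <- by - ay
  el2 <- pmax(ex^2 + ey^2, .Machine$double.eps)
  np <- length(px)
  best <- rep(Inf, np)
  for (k in seq_len(n)) {
    t <- ((px - ax[k]) * ex[k] + (py - ay[k]) * ey[k]) / el2[k]
    t <- pmin(pmax(t, 0), 1)
    dx <- px - (ax[k] + t * ex[k]); dy <- py - (ay[k] + t * ey[k])
    best <- pmin(best, dx * dx + dy * dy)
  }
  sqrt(best)
}

# Distance from point p along unit direction dir to the nearest crossing of
# any polygon in `polys`, searched within (0, maxd]. Returns maxd + 1 when no
# crossing is found (caller treats that as "interior arm").
ray_boundary_distance <- function(p, dir, polys, maxd) {
  best <- maxd + 1
  q <- p + dir * maxd
  for (poly in polys) {
    xy <- poly
    n <- nrow(xy)
    ax <- xy[, 1L]; ay <- xy[, 2L]
    bx <- c(ax[-1L], ax[1L]); by <- c(ay[-1L], ay[1L])
    rx <- q[1L] - p[1L]; ry <- q[2L] - p[2L]
    sx <- bx - ax; sy <- by - ay
    denom <- rx * sy - ry * sx
    ok <- abs(denom) > 1e-14
    t <- ((ax - p[1L]) * sy - (ay - p[2L]) * sx) / denom
    u <- ((ax - p[1L]) * ry - (ay - p[2L]) * rx) / denom
    hit <- ok & t >= 0 & t <= 1 & u >= -1e-12 & u <= 1 + 1e-12
    if (any(hit)) best <- min(best, min(t[hit]) * maxd)
  }
  best
}

#' Regular polygon approximations of circles and ellipses
#'
#' @param r Radius (circle) in mm.
#' @param a,b Semi-axes in mm.
#' @param n Number of vertices.
#' @param centre Length-2 centre.
#' @return n x 2 vertex matrix, counter-clockwise.
#' @export
circle_polygon <- function(r, n = 64L, centre = c(0, 0)) {
  ellipse_polygon(r, r, n = n, centre = centre)
}

#' @rdname circle_polygon
#' @export
ellipse_polygon <- function(a, b, n = 64L, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(centre[1L] + a * cos(th), centre[2L] + b * sin(th))
}
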