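# Polygon geometry in level-0 pixel coordinates (0-based, top-left origin).

#' Polygon area by the shoelace formula
#'
#' @param poly Two-column matrix of vertices (x, y); the polygon is treated
#'   as closed (last vertex joins the first).
#' @return Absolute area in square pixels.
#' @export
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorised even-odd (ray crossing) test; points lying on an edge count as
#' inside (within `eps`), so a patch footprint that exactly matches an
#' axis-aligned annotation is accepted.
#'
#' @param px,py Point coordinates (equal-length vectors).
#' @param poly Two-column vertex matrix, treated as closed.
#' @param eps Boundary tolerance in pixels.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # distance from point to segment (i, j) for the boundary-inclusive rule
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx * dx + dy * dy
    tpar <- if (len2 == 0) rep(0, length(px)) else
      clamp(((px - xi) * dx + (py - yi) * dy) / len2, 0, 1)
    d2 <- (px - (xi + tpar * dx))^2 + (py - (yi + tpar * dy))^2
    on_edge <- on_edge | d2 <= eps^2 * (1 + len2)
    j <- i
  }
  inside | on_edge
}

# Crossing-count-only even-odd test (no boundary tolerance); used for
# rasterization where pixel centres essentially never hit an edge exactly.
pip_crossings <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Rasterize a polygon over an integer pixel grid [x0, x1) x [y0, y1).
# Pixel (r, c) samples the polygon at its centre. Returns a logical matrix of
# (y1 - y0) rows by (x1 - x0) columns.
polygon_raster_mask <- function(poly, x0, y0, x1, y1) {
  xs <- seq(x0, x1 - 1) + 0.5
  ys <- seq(y0, y1 - 1) + 0.5
  nx <- length(xs); ny <- length(ys)
  px <- rep(xs, each = ny)
  py <- rep(ys, times = nx)
  m <- pip_crossings(px, py, as.matrix(poly))
  matrix(m, nrow = ny, ncol = nx)
}

# Star-shaped random polygon: radial perturbation of an ellipse around a
# centre; guaranteed simple (non-self-intersecting).
random_star_polygon <- function(cx, cy, r_mean, n_vertices = 12,
                                irregularity = 0.3, aspect = 1) {
  ang <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  r <- r_mean * (1 + stats::runif(n_vertices, -irregularity, irregularity))
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang) * aspect)
}

# Simplicity check via pairwise proper segment intersection (O(V^2); used to
# validate user-supplied polygons, V is small).
polygon_is_simple <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  ccw <- function(ax, ay, bx, by, cx, cy)
    (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
  for (i in seq_len(n - 1)) {
    for (k in (i + 1):n) {
      if (k == i || k == i %% n + 1 || i == k %% n + 1) next
      a <- seg[i, ]; b <- seg[k, ]
      d1 <- ccw(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- ccw(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- ccw(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- ccw(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(FALSE)
    }
  }
  TRUE
}
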