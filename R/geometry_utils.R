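# Small 2-D polygon primitives used by the contour handling, phantom
# generator and local-frame construction. Polygons are n x 2 matrices of mm
# coordinates, implicitly closed (last vertex connects to first).

# signed area via the shoelace formula; > 0 for counterclockwise winding
polygon_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# ensure counterclockwise winding
normalize_winding <- function(p) {
  if (polygon_signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

# ray-casting point-in-polygon; px, py vectors -> logical vector
points_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    crosses <- ((y[k] > py) != (yn[k] > py))
    if (any(crosses)) {
      xint <- x[k] + (py[crosses] - y[k]) / (yn[k] - y[k]) * (xn[k] - x[k])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

# unsigned distance from each point (px, py) to the closed polyline `poly`
points_polygon_distance <- function(px, py, poly) {
  ax <- poly[, 1]; ay <- poly[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  ex <- bx - ax; ey <- by - ay
  elen2 <- pmax(ex^2 + ey^2, .Machine$double.eps)
  best <- rep(Inf, length(px))
  for (k in seq_along(ax)) {
    t <- ((px - ax[k]) * ex[k] + (py - ay[k]) * ey[k]) / elen2[k]
    t <- pmin(pmax(t, 0), 1)
    dx <- px - (ax[k] + t * ex[k]); dy <- py - (ay[k] + t * ey[k])
    best <- pmin(best, dx * dx + dy * dy)
  }
  sqrt(best)
}

# O(n^2) simple-polygon check: no two non-adjacent edges intersect
polygon_is_simple <- function(p) {
  n <- nrow(p)
  ax <- p[, 1]; ay <- p[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  seg_int <- function(i, j) {
    d1x <- bx[i] - ax[i]; d1y <- by[i] - ay[i]
    d2x <- bx[j] - ax[j]; d2y <- by[j] - ay[j]
    denom <- d1x * d2y - d1y * d2x
    if (abs(denom) < 1e-14) return(FALSE)  # parallel: treat as non-crossing
    t <- ((ax[j] - ax[i]) * d2y - (ay[j] - ay[i]) * d2x) / denom
    u <- ((ax[j] - ax[i]) * d1y - (ay[j] - ay[i]) * d1x) / denom
    t > 1e-12 && t < 1 - 1e-12 && u > 1e-12 && u < 1 - 1e-12
  }
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (seg_int(i, j)) return(FALSE)
    }
  }
  TRUE
}

#' Pixel grid of a short-axis slice
#'
#' Defines the geometry contract used across the package: voxel `(i, j)`
#' (1-based array indices) has its center at world coordinates
#' `((i - 0.5) * dx, (j - 0.5) * dy)` mm.
#'
#' @param dim Integer 2-vector, matrix size in pixels.
#' @param spacing Pixel spacing in mm (scalar or 2-vector).
#' @param thickness Slice thickness in mm.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(dim, spacing = 1, thickness = 8) {
  dim <- as.integer(rep(dim, length.out = 2))
  spacing <- rep(as.numeric(spacing), length.out = 2)
  if (any(dim < 4)) stop("image_grid(): matrix size too small")
  if (any(spacing <= 0) || thickness <= 0) stop("image_grid(): spacing must be > 0")
  structure(list(dim = dim, spacing = spacing, thickness = thickness),
            class = "image_grid")
}

# mm coordinates of all voxel centers, as a list(x = matrix, y = matrix)
grid_centers <- function(grid) {
  xs <- (seq_len(grid$dim[1]) - 0.5) * grid$spacing[1]
  ys <- (seq_len(grid$dim[2]) - 0.5) * grid$spacing[2]
  list(x = matrix(xs, grid$dim[1], grid$dim[2]),
       y = matrix(ys, grid$dim[1], grid$dim[2], byrow = TRUE))
}

# normalize rows of an n x 3 matrix; zero rows left untouched but reported
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  ok <- n > 0
  m[ok, ] <- m[ok, , drop = FALSE] / n[ok]
  m
}
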