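#' Contours of the endocardial border
#'
#' A contour is a closed simple polygon stored as a tibble with columns `x`
#' and `y` (pixel coordinates, one row per vertex; closure is implied, the
#' first vertex is not repeated). Vertices are kept in counterclockwise
#' order, i.e. with positive shoelace signed area in the (x, y) plane.
#'
#' @param x A data frame with numeric columns `x` and `y`, or a two-column
#'   matrix of vertex coordinates.
#' @return A tibble of class `lv_contour` with columns `x`, `y`.
#' @examples
#' tri <- as_contour(data.frame(x = c(0, 4, 0), y = c(0, 0, 3)))
#' polygon_area(tri)
#' @export
as_contour <- function(x) {
  if (is.matrix(x)) x <- tibble(x = x[, 1], y = x[, 2])
  if (!all(c("x", "y") %in% names(x))) {
    abort("a contour needs `x` and `y` columns")
  }
  vx <- as.numeric(x$x)
  vy <- as.numeric(x$y)
  v <- tibble(x = vx, y = vy)
  if (!all(is.finite(v$x)) || !all(is.finite(v$y))) {
    abort("contour vertices must be finite")
  }
  # drop an explicit closing vertex if present
  nv <- nrow(v)
  if (nv >= 2 && v$x[1] == v$x[nv] && v$y[1] == v$y[nv]) v <- v[-nv, ]
  if (nrow(v) < 3) abort("a contour needs at least 3 vertices")
  if (shoelace(v$x, v$y) < 0) v <- v[rev(seq_len(nrow(v))), ]
  class(v) <- c("lv_contour", class(tibble()))
  v
}

# signed shoelace area (positive = counterclockwise in the x/y plane)
shoelace <- function(x, y) {
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area of a contour
#'
#' Shoelace area of the closed polygon, scaled to mm^2 by the pixel spacing.
#' Orientation-independent.
#'
#' @param contour An [as_contour()] polygon (or any data frame with `x`, `y`).
#' @param pixel_spacing Pixel size in mm/pixel.
#' @return Area in mm^2 (a single number).
#' @export
polygon_area <- function(contour, pixel_spacing = 1) {
  contour <- as_contour(contour)
  abs(shoelace(contour$x, contour$y)) * pixel_spacing^2
}

# closed-polygon perimeter in pixel units
contour_perimeter <- function(contour) {
  dx <- diff(c(contour$x, contour$x[1]))
  dy <- diff(c(contour$y, contour$y[1]))
  sum(sqrt(dx^2 + dy^2))
}

#' Resample a contour to equally spaced vertices
#'
#' Arc-length uniform resampling along the closed polygon.
#'
#' @inheritParams polygon_area
#' @param n Number of output vertices.
#' @return An `lv_contour` with `n` vertices.
#' @export
resample_contour <- function(contour, n = 256) {
  contour <- as_contour(contour)
  px <- c(contour$x, contour$x[1])
  py <- c(contour$y, contour$y[1])
  s <- c(0, cumsum(sqrt(diff(px)^2 + diff(py)^2)))
  total <- s[length(s)]
  if (total <= 0) abort("degenerate contour: zero perimeter")
  si <- seq(0, total, length.out = n + 1)[seq_len(n)]
  as_contour(tibble(
    x = approx(s, px, xout = si, ties = "ordered")$y,
    y = approx(s, py, xout = si, ties = "ordered")$y
  ))
}

#' Principal (long) axis of a contour
#'
#' The longest chord between vertex pairs after resampling the contour to 256
#' equally spaced points. Ties are broken deterministically by the smallest
#' starting vertex index.
#'
#' @inheritParams polygon_area
#' @return A list with `a`, `b` (each a named numeric `c(x, y)` endpoint) and
#'   `length` (chord length in pixels).
#' @export
principal_axis <- function(contour) {
  rc <- resample_contour(contour, 256)
  p <- cbind(rc$x, rc$y)
  d2 <- as.matrix(stats::dist(p))^2
  if (max(d2) <= 0) abort("degenerate contour: zero extent")
  hit <- which(d2 == max(d2), arr.ind = TRUE)
  # smallest starting index, then smallest partner index
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  i <- hit[1, 1]; j <- hit[1, 2]
  list(
    a = c(x = p[i, 1], y = p[i, 2]),
    b = c(x = p[j, 1], y = p[j, 2]),
    length = sqrt(d2[i, j])
  )
}

# minimum distance from each point (n x 2 matrix) to a set of segments
# (m x 4 matrix: x1 y1 x2 y2); vectorized over points, loop over segments
point_segment_dist <- function(points, segments) {
  px <- points[, 1]; py <- points[, 2]
  best <- rep(Inf, length(px))
  for (k in seq_len(nrow(segments))) {
    x1 <- segments[k, 1]; y1 <- segments[k, 2]
    x2 <- segments[k, 3]; y2 <- segments[k, 4]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - x1)^2 + (py - y1)^2
    } else {
      t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

contour_segments <- function(contour) {
  x <- contour$x; y <- contour$y
  cbind(x, y, c(x[-1], x[1]), c(y[-1], y[1]))
}

#' Hausdorff distance between two contours
#'
#' Symmetric Hausdorff distance: the larger of the two directed maxima of
#' vertex-to-polygon distances, with both polygons densified to `n` vertices
#' first. Used as the segmentation-accuracy metric.
#'
#' @param a,b Contours.
#' @param n Resampling density.
#' @return Distance in pixel units.
#' @export
hausdorff_distance <- function(a, b, n = 512) {
  a <- resample_contour(a, n)
  b <- resample_contour(b, n)
  sa <- contour_segments(a)
  sb <- contour_segments(b)
  d_ab <- max(point_segment_dist(cbind(a$x, a$y), sb))
  d_ba <- max(point_segment_dist(cbind(b$x, b$y), sa))
  max(d_ab, d_ba)
}
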