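# Pixel coordinate convention used throughout the package: 0-based, origin at
# the top-left corner, x rightward (columns), y downward (rows). The centre of
# array element [r, c] is (x, y) = (c - 1, r - 1). Polygons are closed
# implicitly (last vertex joins the first).

#' Validate and normalise a polygon
#'
#' Coerces a polygon to an n x 2 numeric matrix with columns `x`, `y`,
#' dropping an explicitly repeated closing vertex.
#'
#' @param polygon An n x 2 matrix-like object of vertex coordinates, or a
#'   list of length-2 points.
#' @return An n x 2 numeric matrix with columns `x` and `y`, n >= 3.
#' @keywords internal
as_polygon <- function(polygon) {
  if (is.list(polygon) && !is.data.frame(polygon))
    polygon <- do.call(rbind, lapply(polygon, function(p) as.numeric(p)))
  p <- as.matrix(polygon)
  storage.mode(p) <- "double"
  if (ncol(p) != 2L || anyNA(p) || any(!is.finite(p)))
    stop("polygon must be a finite numeric n x 2 matrix", call. = FALSE)
  n <- nrow(p)
  if (n >= 2L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  if (nrow(p) < 3L)
    stop("polygon must have at least 3 vertices", call. = FALSE)
  colnames(p) <- c("x", "y")
  p
}

#' Signed and absolute polygon area in square pixels (shoelace formula)
#' @param polygon Polygon accepted by [as_polygon()].
#' @return Absolute area in px^2.
#' @keywords internal
polygon_area_px2 <- function(polygon) {
  p <- as_polygon(polygon)
  x <- p[, 1L]; y <- p[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

#' Even-odd point-in-polygon test
#'
#' Ray-casting with the even-odd rule; points exactly on a horizontal edge
#' follow the half-open convention so adjacent polygons do not double-count
#' pixels.
#'
#' @param px,py Numeric vectors of query point coordinates.
#' @param polygon Polygon accepted by [as_polygon()].
#' @return Logical vector, `TRUE` where the point is inside.
#' @keywords internal
point_in_polygon <- function(px, py, polygon) {
  p <- as_polygon(polygon)
  n <- nrow(p)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- p[i, 1L]; yi <- p[i, 2L]
    xj <- p[j, 1L]; yj <- p[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterise a polygon to a logical mask
#'
#' Membership is decided by the even-odd rule applied at pixel centres.
#'
#' @param polygon Polygon in pixel coordinates.
#' @param width,height Raster dimensions in pixels.
#' @return A `height` x `width` logical matrix.
#' @export
polygon_mask <- function(polygon, width, height) {
  p <- as_polygon(polygon)
  mask <- matrix(FALSE, nrow = height, ncol = width)
  c0 <- max(1L, floor(min(p[, 1L])) + 1L)
  c1 <- min(width, ceiling(max(p[, 1L])) + 1L)
  r0 <- max(1L, floor(min(p[, 2L])) + 1L)
  r1 <- min(height, ceiling(max(p[, 2L])) + 1L)
  if (c0 > c1 || r0 > r1) return(mask)
  cols <- c0:c1; rows <- r0:r1
  grid <- expand.grid(r = rows, c = cols)
  inside <- point_in_polygon(grid$c - 1, grid$r - 1, p)
  mask[cbind(grid$r, grid$c)] <- inside
  mask
}

# Proper segment intersection (shared endpoints of adjacent edges excluded by
# the caller). Returns TRUE when the open interiors cross.
segments_cross <- function(a1, a2, b1, b2) {
  d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
  d1 <- d(b1, b2, a1); d2 <- d(b1, b2, a2)
  d3 <- d(a1, a2, b1); d4 <- d(a1, a2, b2)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  FALSE
}

#' Test whether a polygon is simple (non-self-intersecting)
#' @param polygon Polygon accepted by [as_polygon()].
#' @return `TRUE` if no two non-adjacent edges properly cross.
#' @export
is_simple_polygon <- function(polygon) {
  p <- as_polygon(polygon)
  n <- nrow(p)
  edges <- lapply(seq_len(n), function(i) list(p[i, ], p[if (i == n) 1L else i + 1L, ]))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      # skip adjacent edges (share a vertex), including the wrap-around pair
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_cross(edges[[i]][[1]], edges[[i]][[2]],
                         edges[[j]][[1]], edges[[j]][[2]])) return(FALSE)
    }
  }
  TRUE
}

assert_simple_polygon <- function(polygon) {
  p <- as_polygon(polygon)
  if (!is_simple_polygon(p))
    stop("polygon is self-intersecting", call. = FALSE)
  p
}

# Rotate points (n x 2) by `deg` degrees about `center` (counter-clockwise in
# standard axes; in image axes with y downward this appears clockwise).
rotate_points <- function(points, deg, center = c(0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  sweep(sweep(as.matrix(points), 2L, center) %*% t(R), 2L, center, `+`)
}
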