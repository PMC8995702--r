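# Laser fiducial detection and metric calibration.
#
# The laser used clinically emits at 515 nm, so fiducials are detected on a
# green-dominance map: G - max(R, B), clamped at zero, lightly median
# filtered. Blobs/lines are extracted by thresholding and connected-component
# labelling, and located by intensity-weighted (sub-pixel) centroids or
# total-least-squares line fits.

laser_dominance <- function(image, channel = "G") {
  if (length(dim(image)) != 3L || dim(image)[3L] < 3L)
    stop("image must be an H x W x 3 array", call. = FALSE)
  k <- match(channel, c("R", "G", "B"))
  if (is.na(k)) stop("laser channel must be one of R, G, B", call. = FALSE)
  others <- setdiff(1:3, k)
  dom <- image[, , k] - pmax(image[, , others[1L]], image[, , others[2L]])
  pmax(dom, 0)
}

# Exact 3x3 median filter (borders replicated), computed with a 19-exchange
# sorting network over the nine shifted copies; fully vectorized.
median3x3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  shift <- function(dy, dx)
    m[pmin(pmax(seq_len(H) + dy, 1L), H), pmin(pmax(seq_len(W) + dx, 1L), W)]
  x <- list()
  k <- 0L
  for (dy in -1:1) for (dx in -1:1) { k <- k + 1L; x[[k]] <- shift(dy, dx) }
  sw <- function(a, b) {
    lo <- pmin(x[[a]], x[[b]])
    x[[b]] <<- pmax(x[[a]], x[[b]])
    x[[a]] <<- lo
  }
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9)
  sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6)
  sw(5, 8); sw(5, 3); sw(7, 5)
  sw(5, 3)
  x[[5]]
}

dominance_components <- function(image, channel = "G",
                                 min_px = 4L, rel_thresh = 0.30,
                                 abs_thresh = 0.15) {
  dom <- laser_dominance(image, channel)
  dom <- median3x3(dom)
  thr <- max(abs_thresh, rel_thresh * max(dom))
  mask <- dom > thr
  if (!any(mask)) return(list(dom = dom, labels = NULL, ids = integer(0)))
  labels <- as.matrix(EBImage::bwlabel(mask))
  sizes <- tabulate(labels[labels > 0])
  ids <- which(sizes >= min_px)
  list(dom = dom, labels = labels, ids = ids)
}

component_centroid <- function(dom, labels, id) {
  idx <- which(labels == id, arr.ind = TRUE)
  w <- dom[idx]
  c(x = sum((idx[, 2L] - 1) * w) / sum(w),
    y = sum((idx[, 1L] - 1) * w) / sum(w))
}

#' Detect the laser dot pair
#'
#' Thresholds the laser-dominance map, labels connected blobs, and returns
#' the intensity-weighted centroids of the two blobs with the largest
#' integrated dominance, at sub-pixel precision, ordered by x then y.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param channel Laser colour channel, default `"G"`.
#' @param min_px Minimum blob size in pixels.
#' @return A 2 x 2 matrix (columns `x`, `y`) with attribute `quality`, the
#'   mass ratio of the second to the brightest blob (in \[0, 1\]).
#' @export
detect_laser_dots <- function(image, channel = "G", min_px = 4L) {
  cc <- dominance_components(image, channel, min_px)
  if (length(cc$ids) < 2L)
    stop("detection error: fewer than 2 laser blobs found (unusable frame)",
         call. = FALSE)
  mass <- vapply(cc$ids, function(id) sum(cc$dom[cc$labels == id]), numeric(1))
  top <- cc$ids[order(mass, decreasing = TRUE)][1:2]
  cent <- t(vapply(top, function(id) component_centroid(cc$dom, cc$labels, id),
                   numeric(2)))
  ord <- order(cent[, 1L], cent[, 2L])
  cent <- cent[ord, , drop = FALSE]
  colnames(cent) <- c("x", "y")
  attr(cent, "quality") <- min(mass[order(mass, decreasing = TRUE)][2] /
                                 max(mass), 1)
  cent
}

#' Metric scale from the laser dot pair
#'
#' @param dots 2 x 2 matrix of dot centres (pixel coordinates).
#' @param separation_mm Physical dot separation, default 1 mm.
#' @param quality Optional detection confidence in \[0, 1\]; taken from the
#'   `quality` attribute of `dots` when present.
#' @return An object of class `calibration_scale` with fields `mm_per_px`,
#'   `dot_centers`, `quality`.
#' @export
scale_from_dots <- function(dots, separation_mm = 1.0, quality = NULL) {
  dots <- as.matrix(dots)
  if (!all(dim(dots) == c(2L, 2L)))
    stop("dots must be a 2 x 2 matrix", call. = FALSE)
  if (separation_mm <= 0)
    stop("separation_mm must be positive", call. = FALSE)
  d <- sqrt(sum((dots[1L, ] - dots[2L, ])^2))
  if (d == 0)
    stop("calibration error: coincident dot centres", call. = FALSE)
  if (is.null(quality))
    quality <- if (!is.null(attr(dots, "quality"))) attr(dots, "quality") else 1
  structure(list(mm_per_px = separation_mm / d,
                 dot_centers = dots,
                 quality = quality),
            class = "calibration_scale")
}

as_mm_per_px <- function(scale) {
  if (inherits(scale, "calibration_scale")) return(scale$mm_per_px)
  if (is.numeric(scale) && length(scale) == 1L && scale > 0) return(scale)
  stop("scale must be a calibration_scale or a positive number", call. = FALSE)
}

# Weighted total-least-squares line fit to one labelled component.
fit_component_line <- function(dom, labels, id) {
  idx <- which(labels == id, arr.ind = TRUE)
  w <- dom[idx]
  x <- idx[, 2L] - 1; y <- idx[, 1L] - 1
  mx <- sum(w * x) / sum(w); my <- sum(w * y) / sum(w)
  cxx <- sum(w * (x - mx)^2); cyy <- sum(w * (y - my)^2)
  cxy <- sum(w * (x - mx) * (y - my))
  e <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2L, 2L), symmetric = TRUE)
  dir <- e$vectors[, 1L]
  if (dir[2L] < 0) dir <- -dir  # orient downward (increasing y)
  list(point = c(x = mx, y = my), dir = c(x = dir[1L], y = dir[2L]),
       n_px = nrow(idx))
}

line_angle <- function(line) atan2(line$dir[2L], line$dir[1L]) %% pi

angle_dist <- function(a, b) {
  d <- abs(a - b) %% pi
  min(d, pi - d)
}

#' Detect the three-line laser pattern
#'
#' Labels laser-dominant components, fits a total-least-squares line to each,
#' and identifies the pair with the smallest mutual angle as the parallel
#' reference lines; the remaining line is the tilted one.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param tilt_deg Configured rig tilt of the third line (degrees), stored on
#'   the result; default 8.5.
#' @param channel Laser colour channel.
#' @param min_px Minimum component size in pixels.
#' @param parallel_tol_deg Maximum mutual angle for the reference pair.
#' @return An object of class `line_set`: `reference` (list of two lines,
#'   ordered by lateral position), `tilted`, `tilt_deg` (configured) and
#'   `measured_tilt_deg`.
#' @export
detect_laser_lines <- function(image, tilt_deg = 8.5, channel = "G",
                               min_px = 60L, parallel_tol_deg = 3) {
  cc <- dominance_components(image, channel, min_px)
  if (length(cc$ids) != 3L)
    stop(sprintf("detection error: expected 3 laser lines, found %d",
                 length(cc$ids)), call. = FALSE)
  lines <- lapply(cc$ids, function(id) fit_component_line(cc$dom, cc$labels, id))
  angs <- vapply(lines, line_angle, numeric(1))
  pairs <- rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  mut <- apply(pairs, 1L, function(p) angle_dist(angs[p[1L]], angs[p[2L]]))
  best <- which.min(mut)
  if (mut[best] * 180 / pi > parallel_tol_deg)
    stop("detection error: no parallel reference line pair found", call. = FALSE)
  ref_idx <- pairs[best, ]
  tilt_idx <- setdiff(1:3, ref_idx)
  ref <- lines[ref_idx]
  ord <- order(vapply(ref, function(l) l$point[1L], numeric(1)))
  ref <- ref[ord]
  ref_ang <- mean(vapply(ref, line_angle, numeric(1)))
  measured <- angle_dist(ref_ang, angs[tilt_idx]) * 180 / pi
  structure(list(reference = ref, tilted = lines[[tilt_idx]],
                 tilt_deg = tilt_deg, measured_tilt_deg = measured),
            class = "line_set")
}

# x-coordinate of a line at a given y (line must not be horizontal).
line_x_at_y <- function(line, y) {
  if (abs(line$dir[2L]) < 1e-9)
    stop("line is horizontal; cannot evaluate at a row", call. = FALSE)
  t <- (y - line$point[2L]) / line$dir[2L]
  unname(line$point[1L] + t * line$dir[1L])
}

#' Lateral offset of the tilted line from the first reference line
#'
#' The offset is measured perpendicular to the reference-line direction, at
#' the point where the tilted line crosses image row `y`.
#'
#' @param lines A `line_set`.
#' @param y Row (0-based y coordinate) at which to evaluate.
#' @return Signed offset in pixels (positive toward +x).
#' @export
line_offset_px <- function(lines, y) {
  stopifnot(inherits(lines, "line_set"))
  ref <- lines$reference[[1L]]
  n <- c(ref$dir[2L], -ref$dir[1L])          # unit normal of reference dir
  if (n[1L] < 0) n <- -n
  q <- c(line_x_at_y(lines$tilted, y), y)
  unname(sum((q - ref$point) * n))
}

#' Metric scale from the parallel reference line pair
#'
#' @param lines A `line_set`.
#' @param separation_mm Physical separation of the reference lines, mm.
#' @return A `calibration_scale` (dot centres set to the two line base
#'   points).
#' @export
scale_from_lines <- function(lines, separation_mm = 1.0) {
  stopifnot(inherits(lines, "line_set"))
  if (separation_mm <= 0) stop("separation_mm must be positive", call. = FALSE)
  r1 <- lines$reference[[1L]]; r2 <- lines$reference[[2L]]
  n <- c(r1$dir[2L], -r1$dir[1L])
  d <- abs(sum((r2$point - r1$point) * n))
  if (d == 0) stop("calibration error: coincident reference lines", call. = FALSE)
  structure(list(mm_per_px = separation_mm / d,
                 dot_centers = rbind(r1$point, r2$point),
                 quality = 1),
            class = "calibration_scale")
}

#' Depth from the tilted-line lateral offset
#'
#' Triangulation model: a line tilted by `theta` relative to the parallel
#' reference pair shifts laterally by `depth * tan(theta)` between two
#' surfaces separated by `depth` along the viewing axis, so
#' `depth = (far_offset - near_offset) / tan(theta)`. Sign is preserved.
#'
#' @param lines A `line_set`, or a single tilt angle in degrees.
#' @param near_offset_mm,far_offset_mm Lateral offsets of the tilted line
#'   from the reference line on the near and far surface, in mm.
#' @return An object of class `depth_measurement` with `near_offset_mm`,
#'   `far_offset_mm`, `tilt_deg`, `depth_mm`.
#' @export
depth_from_line_offset <- function(lines, near_offset_mm, far_offset_mm) {
  tilt <- if (inherits(lines, "line_set")) lines$tilt_deg else as.numeric(lines)
  if (!is.finite(tilt) || tilt <= 0 || tilt >= 90)
    stop("tilt angle must lie strictly between 0 and 90 degrees", call. = FALSE)
  if (!is.finite(near_offset_mm) || !is.finite(far_offset_mm))
    stop("value error: offsets must be finite", call. = FALSE)
  depth <- (far_offset_mm - near_offset_mm) / tan(tilt * pi / 180)
  structure(list(near_offset_mm = near_offset_mm,
                 far_offset_mm = far_offset_mm,
                 tilt_deg = tilt,
                 depth_mm = depth),
            class = "depth_measurement")
}

#' Measure depth from a two-surface scene
#'
#' Detects the three-line pattern separately on the near (above `split_row`)
#' and far portion of the image, derives the metric scale from the near
#' reference pair, evaluates the tilted-line offsets at the surface boundary,
#' and applies the tangent relation.
#'
#' @param image H x W x 3 array.
#' @param split_row Last image row (1-based) belonging to the near surface.
#' @param separation_mm Reference line separation in mm.
#' @param tilt_deg Rig tilt angle in degrees.
#' @param channel Laser colour channel.
#' @return A list: `depth` (a `depth_measurement`), `scale`
#'   (a `calibration_scale`), `near_lines`, `far_lines`.
#' @export
depth_from_scene <- function(image, split_row, separation_mm = 1.0,
                             tilt_deg = 8.5, channel = "G") {
  H <- dim(image)[1L]
  stopifnot(split_row > 1L, split_row < H)
  near <- image[seq_len(split_row), , , drop = FALSE]
  far <- image[(split_row + 1L):H, , , drop = FALSE]
  nl <- detect_laser_lines(near, tilt_deg, channel)
  fl <- detect_laser_lines(far, tilt_deg, channel)
  # far crop coordinates -> full image coordinates
  fl$reference <- lapply(fl$reference, function(l) {
    l$point[2L] <- l$point[2L] + split_row; l
  })
  fl$tilted$point[2L] <- fl$tilted$point[2L] + split_row
  y_b <- split_row - 0.5
  scale <- scale_from_lines(nl, separation_mm)
  near_off <- line_offset_px(nl, y_b) * scale$mm_per_px
  far_off <- line_offset_px(fl, y_b) * scale$mm_per_px
  list(depth = depth_from_line_offset(tilt_deg, near_off, far_off),
       scale = scale, near_lines = nl, far_lines = fl)
}
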