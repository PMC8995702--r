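# Calibrated morphometry: the seven metric parameters of the glottis and
# oropharyngeal inlet, repeated-evaluation aggregation, and pre/post percent
# change.

morphometry_fields <- c(
  "vocal_length_left_mm", "vocal_length_right_mm",
  "vocal_width_left_mm", "vocal_width_right_mm",
  "vocal_area_left_mm2", "vocal_area_right_mm2",
  "vocal_angle_deg", "glottic_area_mm2", "csaoi_mm2",
  "retropalatal_depth_mm")

#' Construct a morphometry result
#'
#' Named container for the calibrated metric parameters: per-side vocal fold
#' length, width at midpoint, and area; vocal fold angle; glottic area;
#' oropharyngeal inlet area (CSAOI); retropalatal depth. Unmeasured fields
#' are `NA`.
#'
#' @param ... Named values among the morphometry fields.
#' @return Named numeric vector of class `morphometry_result`.
#' @export
morphometry_result <- function(...) {
  vals <- list(...)
  unknown <- setdiff(names(vals), morphometry_fields)
  if (length(unknown))
    stop("unknown morphometry field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- stats::setNames(rep(NA_real_, length(morphometry_fields)),
                         morphometry_fields)
  for (nm in names(vals)) out[nm] <- as.numeric(vals[[nm]])
  lengths_ok <- out[setdiff(morphometry_fields, "vocal_angle_deg")]
  if (any(lengths_ok < 0, na.rm = TRUE))
    stop("lengths and areas must be non-negative", call. = FALSE)
  if (!is.na(out["vocal_angle_deg"]) &&
      (out["vocal_angle_deg"] < 0 || out["vocal_angle_deg"] > 180))
    stop("vocal_angle_deg must lie in [0, 180]", call. = FALSE)
  structure(out, class = "morphometry_result")
}

#' Calibrated polygon area
#'
#' Shoelace area in px^2 scaled by `mm_per_px^2`.
#'
#' @param polygon Simple polygon in pixel coordinates (n >= 3).
#' @param scale A `calibration_scale` or mm-per-pixel number.
#' @return Area in mm^2.
#' @export
polygon_area_mm2 <- function(polygon, scale) {
  p <- assert_simple_polygon(polygon)
  polygon_area_px2(p) * as_mm_per_px(scale)^2
}

#' Vocal fold length, midpoint width, and area
#'
#' Length is the caliper extent of the fold polygon along its principal axis
#' (the direction of largest vertex variance); width is the extent of the
#' polygon's cross-section perpendicular to that axis at 50% of the length;
#' area is the shoelace area. All calibrated to mm via `scale`.
#'
#' @param polygon Simple fold polygon in pixel coordinates.
#' @param scale A `calibration_scale` or mm-per-pixel number.
#' @return Named vector `(length_mm, width_mm, area_mm2)`.
#' @export
vocal_fold_metrics <- function(polygon, scale) {
  p <- assert_simple_polygon(polygon)
  s <- as_mm_per_px(scale)
  ctr <- colMeans(p)
  cen <- sweep(p, 2L, ctr)
  e <- eigen(crossprod(cen) / nrow(p), symmetric = TRUE)
  if (e$values[1L] <= 1e-12)
    stop("geometry error: degenerate (zero-extent) polygon", call. = FALSE)
  ax <- e$vectors[, 1L]; perp <- e$vectors[, 2L]
  u <- as.numeric(cen %*% ax)
  v <- as.numeric(cen %*% perp)
  len_px <- max(u) - min(u)
  if (len_px <= 0)
    stop("geometry error: degenerate (zero-extent) polygon", call. = FALSE)
  u_mid <- (max(u) + min(u)) / 2
  n <- nrow(p)
  vc <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    u1 <- u[i]; u2 <- u[j]
    if (u1 == u2) {
      if (u1 == u_mid) vc <- c(vc, v[i], v[j])
    } else if ((u1 - u_mid) * (u2 - u_mid) <= 0) {
      t <- (u_mid - u1) / (u2 - u1)
      vc <- c(vc, v[i] + t * (v[j] - v[i]))
    }
  }
  if (length(vc) < 2L)
    stop("geometry error: midpoint cross-section not found", call. = FALSE)
  width_px <- max(vc) - min(vc)
  if (width_px <= 0)
    stop("geometry error: degenerate (zero-extent) polygon", call. = FALSE)
  c(length_mm = len_px * s,
    width_mm = width_px * s,
    area_mm2 = polygon_area_px2(p) * s^2)
}

#' Vocal fold angle at the anterior commissure
#'
#' Interior angle between the rays from the anterior commissure to the two
#' vocal process landmarks.
#'
#' @param anterior_commissure,left_process,right_process Length-2 points in
#'   pixel coordinates.
#' @return Angle in degrees, in \[0, 180\].
#' @export
vocal_angle <- function(anterior_commissure, left_process, right_process) {
  ac <- as.numeric(anterior_commissure)
  v1 <- as.numeric(left_process) - ac
  v2 <- as.numeric(right_process) - ac
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("geometry error: coincident landmark points", call. = FALSE)
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(min(max(cosang, -1), 1)) * 180 / pi
}

#' Retropalatal depth from the tilted-line offsets
#'
#' Applies the tangent triangulation relation to the lateral offsets of the
#' tilted laser line measured at the palate (near) and posterior pharyngeal
#' wall (far); returns the absolute depth.
#'
#' @param lines A `line_set` (or tilt angle in degrees).
#' @param palate_offset_mm,posterior_wall_offset_mm Offsets in mm.
#' @return Depth in mm (non-negative).
#' @export
retropalatal_depth <- function(lines, palate_offset_mm, posterior_wall_offset_mm) {
  abs(depth_from_line_offset(lines, palate_offset_mm,
                             posterior_wall_offset_mm)$depth_mm)
}

#' Field-wise maximum over repeated evaluations
#'
#' The clinical protocol repeats each evaluation (at least three times) and
#' keeps the maximum of every parameter; maxima of different fields may come
#' from different evaluations. `NA` fields are ignored unless a field is
#' `NA` in every evaluation.
#'
#' @param evaluations Non-empty list of [morphometry_result()] vectors.
#' @return A `morphometry_result` of field-wise maxima.
#' @export
aggregate_max <- function(evaluations) {
  if (!is.list(evaluations) || length(evaluations) == 0L)
    stop("value error: need at least one evaluation", call. = FALSE)
  mat <- do.call(rbind, lapply(evaluations, function(e) {
    e <- unclass(e)
    stats::setNames(e[morphometry_fields], morphometry_fields)
  }))
  out <- apply(mat, 2L, function(col)
    if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE))
  structure(out, class = "morphometry_result")
}

#' Pre/post percent change
#'
#' Ratio convention: the pre-operative value is 100%, so the returned value
#' is `100 * post / pre`. With `signed = TRUE` the signed relative change
#' `100 * (post - pre) / pre` is returned instead.
#'
#' @param pre_value,post_value Measurements; `pre_value` must be positive.
#' @param signed Return the signed change instead of the ratio.
#' @return Percent value(s).
#' @export
percent_change <- function(pre_value, post_value, signed = FALSE) {
  if (any(!is.finite(pre_value)) || any(pre_value <= 0))
    stop("value error: pre_value must be positive and finite", call. = FALSE)
  if (signed) 100 * (post_value - pre_value) / pre_value
  else 100 * post_value / pre_value
}

#' Laryngeal morphometry from annotations
#'
#' Computes the per-side fold metrics, the vocal angle (when the three
#' landmarks are present), and the glottic area from a list of region
#' annotations plus a calibration scale.
#'
#' @param annotations List of [region_annotation()] objects.
#' @param scale A `calibration_scale` or mm-per-pixel number.
#' @return A [morphometry_result()].
#' @export
laryngeal_morphometry <- function(annotations, scale) {
  byl <- stats::setNames(annotations,
                         vapply(annotations, function(a) a$label, character(1)))
  out <- list()
  if (!is.null(byl$vocal_fold_left)) {
    m <- vocal_fold_metrics(byl$vocal_fold_left$polygon, scale)
    out$vocal_length_left_mm <- m["length_mm"]
    out$vocal_width_left_mm <- m["width_mm"]
    out$vocal_area_left_mm2 <- m["area_mm2"]
  }
  if (!is.null(byl$vocal_fold_right)) {
    m <- vocal_fold_metrics(byl$vocal_fold_right$polygon, scale)
    out$vocal_length_right_mm <- m["length_mm"]
    out$vocal_width_right_mm <- m["width_mm"]
    out$vocal_area_right_mm2 <- m["area_mm2"]
  }
  if (!is.null(byl$glottis))
    out$glottic_area_mm2 <- polygon_area_mm2(byl$glottis$polygon, scale)
  if (!is.null(byl$oropharyngeal_inlet))
    out$csaoi_mm2 <- polygon_area_mm2(byl$oropharyngeal_inlet$polygon, scale)
  lm <- NULL
  for (a in annotations) if (!is.null(a$landmarks)) lm <- a$landmarks
  if (!is.null(lm) &&
      all(c("anterior_commissure", "left_process", "right_process") %in% names(lm)))
    out$vocal_angle_deg <- vocal_angle(lm$anterior_commissure,
                                       lm$left_process, lm$right_process)
  do.call(morphometry_result, out)
}
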