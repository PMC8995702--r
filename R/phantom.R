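#' Phantom scene configuration
#'
#' Describes a synthetic laryngeal or oropharyngeal scene: raster size, the
#' true metric scale, the laser rig constants (1 mm dot-pair separation,
#' 8.5 degree line tilt), scene geometry in millimetres, and the unitless
#' inflammation level that drives mucosal redness and texture roughness.
#'
#' Geometry defaults are derived from the metric field of view
#' (`image_width * mm_per_px_true` by `image_height * mm_per_px_true`) so a
#' scene remains well formed at any plausible scale. The inflammation
#' parameter shifts the mucosal base colour toward red and increases both the
#' fine-grain noise amplitude and the coarse blotch amplitude of the affected
#' regions; the interarytenoid region receives the full effect and the vocal
#' folds an attenuated one, mirroring where an endotracheal tube rests.
#'
#' @param image_width,image_height Raster size in pixels.
#' @param mm_per_px_true True metric scale of the scene (mm per pixel).
#' @param dot_separation_mm Physical separation of the laser dot pair (and of
#'   the parallel reference lines), in mm.
#' @param line_tilt_deg Tilt of the third laser line relative to the parallel
#'   pair, degrees, strictly between 0 and 90.
#' @param glottis_polygon_mm Optional glottal-gap polygon in mm (n x 2); when
#'   `NULL` a spindle-shaped gap is built from the field of view.
#' @param fold_length_mm,fold_width_mm Vocal fold rectangle dimensions in mm
#'   (per side); defaults derived from the field of view.
#' @param fold_angle_deg Full angle between the left and right fold axes at
#'   the anterior commissure, degrees.
#' @param inflammation Unitless severity in \[0, 1\].
#' @param depth_offset_mm Depth difference between the near and far surface of
#'   an oropharyngeal scene, mm (>= 0).
#' @param noise_sd Standard deviation of per-pixel sensor noise (intensity
#'   units on the \[0, 1\] scale).
#' @param subject_color_sd Between-subject standard deviation of the mucosal
#'   base colour (red channel, intensity units).
#' @param subject_texture_sd Between-subject log-scale standard deviation of
#'   the texture amplitude multiplier.
#' @param seed Integer seed; identical config + seed gives a bit-identical
#'   scene.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_width = 480L, image_height = 360L,
                           mm_per_px_true = 0.05,
                           dot_separation_mm = 1.0,
                           line_tilt_deg = 8.5,
                           glottis_polygon_mm = NULL,
                           fold_length_mm = NULL,
                           fold_width_mm = NULL,
                           fold_angle_deg = 20,
                           inflammation = 0,
                           depth_offset_mm = 10,
                           noise_sd = 0.01,
                           subject_color_sd = 0.02,
                           subject_texture_sd = 0.15,
                           seed = 1L) {
  if (image_width <= 0 || image_height <= 0)
    stop("config error: image dimensions must be positive", call. = FALSE)
  if (mm_per_px_true <= 0)
    stop("config error: mm_per_px_true must be positive", call. = FALSE)
  if (dot_separation_mm <= 0)
    stop("config error: dot_separation_mm must be positive", call. = FALSE)
  if (inflammation < 0 || inflammation > 1)
    stop("config error: inflammation must lie in [0, 1]", call. = FALSE)
  if (noise_sd < 0)
    stop("config error: noise_sd must be non-negative", call. = FALSE)
  if (depth_offset_mm < 0)
    stop("config error: depth_offset_mm must be non-negative", call. = FALSE)
  if (line_tilt_deg <= 0 || line_tilt_deg >= 90)
    stop("config error: line_tilt_deg must lie strictly between 0 and 90",
         call. = FALSE)
  if (fold_angle_deg <= 0 || fold_angle_deg >= 120)
    stop("config error: fold_angle_deg must lie in (0, 120)", call. = FALSE)
  if (!is.null(glottis_polygon_mm)) {
    glottis_polygon_mm <- as_polygon(glottis_polygon_mm)
    if (polygon_area_px2(glottis_polygon_mm) <= 0)
      stop("config error: glottis polygon vertices are collinear", call. = FALSE)
  }
  structure(list(
    image_width = as.integer(image_width),
    image_height = as.integer(image_height),
    mm_per_px_true = mm_per_px_true,
    dot_separation_mm = dot_separation_mm,
    line_tilt_deg = line_tilt_deg,
    glottis_polygon_mm = glottis_polygon_mm,
    fold_length_mm = fold_length_mm,
    fold_width_mm = fold_width_mm,
    fold_angle_deg = fold_angle_deg,
    inflammation = inflammation,
    depth_offset_mm = depth_offset_mm,
    noise_sd = noise_sd,
    subject_color_sd = subject_color_sd,
    subject_texture_sd = subject_texture_sd,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

# Zero-mean, unit-variance smooth noise field. Coarse fields (sigma >= 4) are
# generated at quarter resolution and bilinearly upsampled, which preserves
# the correlation structure while keeping generation fast.
smooth_noise <- function(h, w, sigma) {
  if (sigma >= 4) {
    f <- 4L
    hs <- ceiling(h / f) + 2L
    ws <- ceiling(w / f) + 2L
    n <- matrix(stats::rnorm(hs * ws), hs, ws)
    n <- EBImage::gblur(n, sigma / f)
    n <- as.matrix(EBImage::resize(n, w = h, h = w))  # EBImage dim 1 = "w"
    n <- n[seq_len(h), seq_len(w)]
  } else {
    n <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w), sigma)
  }
  (n - mean(n)) / stats::sd(n)
}

# Blend a Gaussian laser blob into the image (mix toward the laser colour).
laser_color <- c(0.05, 1.0, 0.05)  # 515 nm: essentially pure green

stamp_dot <- function(img, cx, cy, sigma = 2) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  r0 <- max(1L, floor(cy - 5 * sigma) + 1L); r1 <- min(h, ceiling(cy + 5 * sigma) + 1L)
  c0 <- max(1L, floor(cx - 5 * sigma) + 1L); c1 <- min(w, ceiling(cx + 5 * sigma) + 1L)
  if (r0 > r1 || c0 > c1) return(img)
  ys <- (r0:r1) - 1; xs <- (c0:c1) - 1
  m <- exp(-(outer((ys - cy)^2, (xs - cx)^2, `+`)) / (2 * sigma^2))
  for (k in 1:3)
    img[r0:r1, c0:c1, k] <- (1 - m) * img[r0:r1, c0:c1, k] + m * laser_color[k]
  img
}

# Blend a laser line given a per-pixel distance matrix (px) to the line.
stamp_line_dist <- function(img, dist, sigma = 1.5) {
  m <- exp(-dist^2 / (2 * sigma^2))
  for (k in 1:3)
    img[, , k] <- (1 - m) * img[, , k] + m * laser_color[k]
  img
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Scene geometry (all in mm) for a laryngeal phantom.
laryngeal_layout <- function(config) {
  s <- config$mm_per_px_true
  fw <- config$image_width * s
  fh <- config$image_height * s
  beta <- config$fold_angle_deg / 2 * pi / 180
  Lf <- if (is.null(config$fold_length_mm)) 0.44 * fh else config$fold_length_mm
  Wf <- if (is.null(config$fold_width_mm)) 0.38 * Lf else config$fold_width_mm
  if (Lf <= 0 || Wf <= 0)
    stop("config error: fold dimensions must be positive", call. = FALSE)
  P0 <- c(fw / 2, 0.18 * fh)                      # anterior commissure
  d_l <- c(-sin(beta), cos(beta))                 # left fold axis (posterior)
  d_r <- c(sin(beta), cos(beta))
  Lg <- 0.95 * Lf
  glottis <- config$glottis_polygon_mm
  if (is.null(glottis)) {
    wh <- 0.5 * Lg * tan(beta) + 0.03 * fh        # glottal half width
    glottis <- rbind(P0,
                     P0 + c(wh, 0.55 * Lg),
                     P0 + c(0.6 * wh, Lg),
                     P0 + c(-0.6 * wh, Lg),
                     P0 + c(-wh, 0.55 * Lg))
  }
  inner <- max(glottis[, 1L]) - P0[1L]
  n_l <- c(-cos(beta), -sin(beta))                # outward normal, left side
  n_r <- c(cos(beta), -sin(beta))
  off <- inner * 0.85
  fold_left <- rbind(P0 + n_l * off,
                     P0 + n_l * off + d_l * Lf,
                     P0 + n_l * (off + Wf) + d_l * Lf,
                     P0 + n_l * (off + Wf))
  fold_right <- rbind(P0 + n_r * off,
                      P0 + n_r * off + d_r * Lf,
                      P0 + n_r * (off + Wf) + d_r * Lf,
                      P0 + n_r * (off + Wf))
  interarytenoid <- rbind(c(0.30 * fw, 0.70 * fh), c(0.72 * fw, 0.70 * fh),
                          c(0.72 * fw, 0.86 * fh), c(0.30 * fw, 0.86 * fh))
  dots <- rbind(c(0.20 * fw, 0.14 * fh),
                c(0.20 * fw + config$dot_separation_mm, 0.14 * fh))
  landmarks <- list(anterior_commissure = P0,
                    left_process = P0 + d_l * Lg,
                    right_process = P0 + d_r * Lg)
  morph <- morphometry_result(
    vocal_length_left_mm = Lf, vocal_length_right_mm = Lf,
    vocal_width_left_mm = Wf, vocal_width_right_mm = Wf,
    vocal_area_left_mm2 = Lf * Wf, vocal_area_right_mm2 = Lf * Wf,
    vocal_angle_deg = config$fold_angle_deg,
    glottic_area_mm2 = polygon_area_px2(glottis))  # shoelace on mm coords
  list(glottis = glottis, fold_left = fold_left, fold_right = fold_right,
       interarytenoid = interarytenoid, dots = dots, landmarks = landmarks,
       morphometry = morph)
}

check_inside_raster <- function(poly_px, w, h, what) {
  if (min(poly_px[, 1L]) < 0 || max(poly_px[, 1L]) > w - 1 ||
      min(poly_px[, 2L]) < 0 || max(poly_px[, 2L]) > h - 1)
    stop(sprintf("geometry error: %s polygon lies outside the raster", what),
         call. = FALSE)
  invisible(poly_px)
}

#' Generate a synthetic laryngeal scene
#'
#' Renders an endoscopy-like laryngeal still: textured mucosa, a dark glottal
#' gap between two vocal folds, an interarytenoid band, and two green laser
#' dots whose centre-to-centre pixel distance encodes the true metric scale
#' (`dot_separation_mm / mm_per_px_true`). Mean red intensity and texture
#' amplitude of the fold and interarytenoid regions increase strictly with
#' `config$inflammation`. The returned ground truth carries the true scale,
#' region polygons (pixel coordinates), landmarks, dot centres, and the true
#' morphometry in mm.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_scene`: list with `image`
#'   (height x width x 3 array in \[0, 1\]) and `truth`.
#' @export
generate_laryngeal_scene <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  lay <- laryngeal_layout(config)
  H <- config$image_height; W <- config$image_width
  s <- config$mm_per_px_true
  px <- function(p) {
    q <- as.matrix(p) / s
    dim(q) <- dim(as.matrix(p))
    q
  }
  polys <- list(glottis = px(lay$glottis),
                vocal_fold_left = px(lay$fold_left),
                vocal_fold_right = px(lay$fold_right),
                interarytenoid = px(lay$interarytenoid))
  for (nm in names(polys)) check_inside_raster(polys[[nm]], W, H, nm)
  dots_px <- px(lay$dots)

  set.seed(config$seed)
  fine <- smooth_noise(H, W, 1.2)
  coarse <- smooth_noise(H, W, 8)
  jit_col <- stats::rnorm(3) * config$subject_color_sd * c(1, 0.5, 0.4)
  jit_tex <- exp(stats::rnorm(1, 0, config$subject_texture_sd))
  sensor <- array(stats::rnorm(H * W * 3), c(H, W, 3)) * config$noise_sd

  base <- c(0.68, 0.50, 0.46) + jit_col
  chw <- c(1, 0.45, 0.40)  # inflammation texture expresses mostly in red
  img <- array(0, c(H, W, 3))
  for (k in 1:3)
    img[, , k] <- base[k] + chw[k] * jit_tex * (0.030 * fine + 0.020 * coarse)

  masks <- lapply(polys, function(p) polygon_mask(p, W, H))
  add_effect <- function(img, mask, e) {
    shift <- c(0.16, -0.05, -0.04) * e
    af <- 0.012 + 0.075 * e   # fine-grain roughness
    ac <- 0.110 * e           # coarse red blotches
    for (k in 1:3)
      img[, , k][mask] <- img[, , k][mask] + shift[k] +
        chw[k] * jit_tex * (af * fine[mask] + ac * coarse[mask])
    img
  }
  img <- add_effect(img, masks$interarytenoid, config$inflammation)
  img <- add_effect(img, masks$vocal_fold_left, 0.35 * config$inflammation)
  img <- add_effect(img, masks$vocal_fold_right, 0.35 * config$inflammation)
  dark <- c(0.07, 0.04, 0.05)
  for (k in 1:3)
    img[, , k][masks$glottis] <- dark[k] + 0.01 * fine[masks$glottis]
  img <- clip01(img + sensor)
  img <- stamp_dot(img, dots_px[1L, 1L], dots_px[1L, 2L])
  img <- stamp_dot(img, dots_px[2L, 1L], dots_px[2L, 2L])
  img <- clip01(img)

  truth <- list(
    scene_type = "laryngeal",
    mm_per_px = s,
    dot_centers_px = dots_px,
    regions = polys,
    landmarks_px = lapply(lay$landmarks, function(p) as.numeric(p) / s),
    morphometry_mm = lay$morphometry,
    inflammation = config$inflammation,
    seed = config$seed
  )
  structure(list(image = img, truth = truth), class = "phantom_scene")
}

#' Generate a synthetic oropharyngeal scene
#'
#' Renders two surfaces at different depths (near on top, far below) crossed
#' by three laser lines: two parallel reference lines separated by
#' `dot_separation_mm`, and one line tilted by `line_tilt_deg`. On the far
#' surface the tilted line is displaced laterally by
#' `depth_offset_mm * tan(line_tilt_deg)` millimetres relative to its
#' near-surface course, which is the triangulation signal used to recover
#' depth. A polygonal oropharyngeal inlet of known area sits on the far
#' surface.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_scene`.
#' @export
generate_oropharyngeal_scene <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$image_height; W <- config$image_width
  s <- config$mm_per_px_true
  theta <- config$line_tilt_deg * pi / 180
  split_row <- floor(H / 2)                    # rows 1..split_row are "near"
  y_split <- split_row - 0.5                   # boundary in 0-based y

  sep_px <- config$dot_separation_mm / s
  x_ref1 <- 0.30 * W
  x_ref2 <- x_ref1 + sep_px
  x_tilt0 <- 0.58 * W                 # tilted line x at the surface boundary
  shift_px <- config$depth_offset_mm * tan(theta) / s
  if (x_tilt0 + shift_px > W - 3 || x_tilt0 < 2)
    stop("geometry error: tilted line leaves the raster; reduce depth_offset_mm",
         call. = FALSE)

  set.seed(config$seed)
  fine <- smooth_noise(H, W, 1.5)
  sensor <- array(stats::rnorm(H * W * 3), c(H, W, 3)) * config$noise_sd

  base <- c(0.70, 0.52, 0.48)
  img <- array(0, c(H, W, 3))
  far <- row(matrix(0, H, W)) > split_row
  for (k in 1:3) {
    ch <- base[k] + 0.025 * fine
    ch[far] <- ch[far] * 0.78                  # far surface is darker
    img[, , k] <- ch
  }

  # inlet polygon (hexagon) on the far surface, in mm
  fw <- W * s; fh <- H * s
  ang <- seq(0, 2 * pi, length.out = 7L)[-7L]
  r_mm <- 0.10 * fh
  inlet_mm <- cbind(0.70 * fw + r_mm * cos(ang), 0.78 * fh + 0.8 * r_mm * sin(ang))
  inlet_px <- inlet_mm / s
  check_inside_raster(inlet_px, W, H, "oropharyngeal_inlet")
  m_inlet <- polygon_mask(inlet_px, W, H)
  dark <- c(0.12, 0.06, 0.07)
  for (k in 1:3) img[, , k][m_inlet] <- dark[k] + 0.01 * fine[m_inlet]

  img <- clip01(img + sensor)

  X <- matrix(0:(W - 1), H, W, byrow = TRUE)
  Y <- matrix(0:(H - 1), H, W)
  img <- stamp_line_dist(img, abs(X - x_ref1))
  img <- stamp_line_dist(img, abs(X - x_ref2))
  # tilted line: through (x_tilt0, y_split), direction (sin theta, cos theta);
  # far course shifted by shift_px toward +x
  d_near <- abs((X - x_tilt0) * cos(theta) - (Y - y_split) * sin(theta))
  d_far <- abs((X - x_tilt0 - shift_px) * cos(theta) - (Y - y_split) * sin(theta))
  d_tilt <- ifelse(far, d_far, d_near)
  img <- stamp_line_dist(img, d_tilt)
  img <- clip01(img)

  truth <- list(
    scene_type = "oropharyngeal",
    mm_per_px = s,
    split_row = split_row,
    y_split = y_split,
    depth_offset_mm = config$depth_offset_mm,
    line_tilt_deg = config$line_tilt_deg,
    x_ref_px = c(x_ref1, x_ref2),
    x_tilt0_px = x_tilt0,
    shift_px = shift_px,
    regions = list(oropharyngeal_inlet = inlet_px),
    csaoi_mm2 = polygon_area_px2(inlet_mm),
    seed = config$seed
  )
  structure(list(image = img, truth = truth), class = "phantom_scene")
}

#' Inflammation effect sizes for a phantom cohort
#'
#' Pre-operative and post-operative inflammation levels are drawn from
#' truncated normal distributions on \[0, 1\].
#'
#' @param pre_mean,post_mean Class means of the inflammation level.
#' @param sd Common standard deviation before truncation.
#' @return An object of class `inflammation_effect`.
#' @export
inflammation_effect <- function(pre_mean = 0.15, post_mean = 0.65, sd = 0.10) {
  stopifnot(pre_mean >= 0, pre_mean <= 1, post_mean >= 0, post_mean <= 1, sd >= 0)
  structure(list(pre_mean = pre_mean, post_mean = post_mean, sd = sd),
            class = "inflammation_effect")
}

rtruncnorm01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(min(max(mean, 0), 1), n))
  u <- stats::runif(n, stats::pnorm(0, mean, sd), stats::pnorm(1, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a paired pre/post phantom cohort
#'
#' Draws `n_per_class` pre-operative and `n_per_class` post-operative
#' laryngeal scenes. Each scene gets its own seed derived from the master
#' seed; inflammation levels are truncated-normal draws around the class
#' means of `effect`.
#'
#' @param n_per_class Number of subjects per class (>= 1).
#' @param effect An [inflammation_effect()].
#' @param seed Master integer seed.
#' @param config Base [phantom_config()]; its `inflammation` and `seed` are
#'   overridden per scene.
#' @return A list of length `2 * n_per_class`; each element has `scene`,
#'   `label` ("pre"/"post"), `subject`, and `inflammation`.
#' @export
generate_cohort <- function(n_per_class, effect = inflammation_effect(),
                            seed = 1L, config = phantom_config()) {
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  stopifnot(inherits(effect, "inflammation_effect"))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_per_class)
  infl <- c(rtruncnorm01(n_per_class, effect$pre_mean, effect$sd),
            rtruncnorm01(n_per_class, effect$post_mean, effect$sd))
  labels <- rep(c("pre", "post"), each = n_per_class)
  subjects <- rep(seq_len(n_per_class), 2L)
  lapply(seq_len(2L * n_per_class), function(i) {
    cfg <- config
    cfg$inflammation <- infl[i]
    cfg$seed <- seeds[i]
    list(scene = generate_laryngeal_scene(cfg),
         label = labels[i], subject = subjects[i], inflammation = infl[i])
  })
}
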