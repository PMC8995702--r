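# Region colour and texture quantification: sRGB -> CIELab conversion,
# gray-level co-occurrence matrices (GLCM), and the four Haralick-style
# features used downstream (energy, contrast, correlation, homogeneity).

region_labels <- c("vocal_fold_left", "vocal_fold_right", "interarytenoid",
                   "glottis", "oropharyngeal_inlet")

#' Region annotation
#'
#' A labelled polygon in pixel coordinates, with optional named landmark
#' points (`anterior_commissure`, `left_process`, `right_process`).
#'
#' @param label One of `"vocal_fold_left"`, `"vocal_fold_right"`,
#'   `"interarytenoid"`, `"glottis"`, `"oropharyngeal_inlet"`.
#' @param polygon Simple polygon (n x 2, n >= 3) in pixel coordinates.
#' @param landmarks Optional named list of length-2 numeric points.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(label, polygon, landmarks = NULL) {
  if (!label %in% region_labels)
    stop(sprintf("parse error: unknown region label '%s' (field: label)", label),
         call. = FALSE)
  polygon <- assert_simple_polygon(polygon)
  if (!is.null(landmarks)) {
    if (is.null(names(landmarks)) || any(names(landmarks) == ""))
      stop("parse error: landmarks must be named (field: landmarks)", call. = FALSE)
    landmarks <- lapply(landmarks, function(p) {
      p <- as.numeric(p)
      if (length(p) != 2L || anyNA(p))
        stop("parse error: landmark must be a finite [x, y] pair (field: landmarks)",
             call. = FALSE)
      p
    })
  }
  structure(list(label = label, polygon = polygon, landmarks = landmarks),
            class = "region_annotation")
}

# sRGB linearisation and the sRGB -> XYZ matrix (D65). The white point is
# taken as the row sums of the matrix so that (1,1,1) maps exactly onto it.
srgb_to_xyz_matrix <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), nrow = 3L, byrow = TRUE)

#' Convert sRGB colours to CIELab (D65)
#'
#' Two-stage mapping: gamma-expanded sRGB to CIE XYZ via the D65 matrix, then
#' XYZ to CIELab with the standard cube-root compression. Neutral inputs
#' (r = g = b) map exactly onto the L* axis (a* = b* = 0).
#'
#' @param rgb Length-3 vector or n x 3 matrix of sRGB components in \[0, 1\].
#' @return Named length-3 vector `(L_star, a_star, b_star)` or an n x 3
#'   matrix with those columns. L* lies in \[0, 100\].
#' @export
rgb_to_cielab <- function(rgb) {
  vec <- is.null(dim(rgb))
  m <- if (vec) matrix(as.numeric(rgb), nrow = 1L) else as.matrix(rgb)
  if (ncol(m) != 3L)
    stop("rgb must have 3 components", call. = FALSE)
  if (anyNA(m) || any(m < -1e-9) || any(m > 1 + 1e-9))
    stop("value error: rgb components must lie in [0, 1]", call. = FALSE)
  m <- pmin(pmax(m, 0), 1)
  lin <- ifelse(m <= 0.04045, m / 12.92, ((m + 0.055) / 1.055)^2.4)
  xyz <- lin %*% t(srgb_to_xyz_matrix)
  wp <- rowSums(srgb_to_xyz_matrix)
  tt <- sweep(xyz, 2L, wp, `/`)
  delta <- 6 / 29
  f <- ifelse(tt > delta^3, tt^(1 / 3), tt / (3 * delta^2) + 4 / 29)
  L <- 116 * f[, 2L] - 16
  a <- 500 * (f[, 1L] - f[, 2L])
  b <- 200 * (f[, 2L] - f[, 3L])
  out <- cbind(L_star = L, a_star = a, b_star = b)
  if (vec) out[1L, ] else out
}

#' GLCM parameters
#'
#' @param levels Number of gray levels (quantization bins), >= 2.
#' @param offsets Integer matrix of displacement vectors, one per row, as
#'   `(dy, dx)`; defaults to the four unit-distance directions
#'   (0,1), (1,0), (1,1), (1,-1).
#' @param symmetric Count each pair in both orders.
#' @param range Intensity range used for equal-width quantization; the
#'   default `c(0, 1)` matches images on the \[0, 1\] scale. `NULL` uses the
#'   observed region range.
#' @return An object of class `glcm_params`.
#' @export
glcm_params <- function(levels = 8L,
                        offsets = rbind(c(0L, 1L), c(1L, 0L),
                                        c(1L, 1L), c(1L, -1L)),
                        symmetric = TRUE, range = c(0, 1)) {
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  offsets <- as.matrix(offsets)
  if (nrow(offsets) < 1L || any(rowSums(abs(offsets)) == 0))
    stop("offsets must be non-empty and non-zero", call. = FALSE)
  structure(list(levels = as.integer(levels), offsets = offsets,
                 symmetric = isTRUE(symmetric), range = range),
            class = "glcm_params")
}

quantize_levels <- function(values, levels, range = c(0, 1)) {
  if (is.null(range)) range <- base::range(values, na.rm = TRUE)
  if (range[2L] <= range[1L]) return(rep(1L, length(values)))
  q <- floor((values - range[1L]) / (range[2L] - range[1L]) * levels) + 1L
  pmin(pmax(q, 1L), as.integer(levels))
}

#' Gray-level co-occurrence matrix
#'
#' Quantizes intensities into `params$levels` equal-width bins, counts
#' co-occurring level pairs at each displacement offset (optionally
#' restricted to a mask, e.g. a polygon region), symmetrizes if requested,
#' and normalizes each offset's matrix to sum 1.
#'
#' @param region Single-channel numeric matrix.
#' @param params A [glcm_params()].
#' @param mask Optional logical matrix of the same size; only pairs with both
#'   pixels inside the mask are counted.
#' @return An object of class `glcm`: `p` is a `levels x levels x n_offsets`
#'   array of normalized matrices.
#' @export
glcm <- function(region, params = glcm_params(), mask = NULL) {
  region <- as.matrix(region)
  stopifnot(inherits(params, "glcm_params"))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(region), ncol(region))
  if (sum(mask) < 2L)
    stop("region error: fewer than 2 pixels in region", call. = FALSE)
  L <- params$levels
  q <- matrix(quantize_levels(region, L, params$range),
              nrow(region), ncol(region))
  H <- nrow(q); W <- ncol(q)
  K <- nrow(params$offsets)
  p <- array(0, c(L, L, K))
  for (k in seq_len(K)) {
    dy <- params$offsets[k, 1L]; dx <- params$offsets[k, 2L]
    rs <- seq(max(1L, 1L - dy), min(H, H - dy))
    cs <- seq(max(1L, 1L - dx), min(W, W - dx))
    if (length(rs) == 0L || length(cs) == 0L)
      stop("region error: offset larger than region", call. = FALSE)
    a <- q[rs, cs, drop = FALSE]
    b <- q[rs + dy, cs + dx, drop = FALSE]
    ok <- mask[rs, cs, drop = FALSE] & mask[rs + dy, cs + dx, drop = FALSE]
    if (!any(ok))
      stop("region error: no pixel pairs available for an offset", call. = FALSE)
    idx <- a[ok] + (b[ok] - 1L) * L
    M <- matrix(tabulate(idx, nbins = L * L), L, L)
    if (params$symmetric) M <- M + t(M)
    p[, , k] <- M / sum(M)
  }
  structure(list(p = p, levels = L, offsets = params$offsets,
                 symmetric = params$symmetric, range = params$range),
            class = "glcm")
}

texture_features_one <- function(P) {
  if (any(P < -1e-12) || abs(sum(P) - 1) > 1e-8)
    stop("value error: co-occurrence matrix must be normalized (sum 1, entries >= 0)",
         call. = FALSE)
  L <- nrow(P)
  i <- seq_len(L)
  D <- outer(i, i, `-`)
  pi_ <- rowSums(P); pj <- colSums(P)
  mui <- sum(i * pi_); muj <- sum(i * pj)
  sdi <- sqrt(sum((i - mui)^2 * pi_)); sdj <- sqrt(sum((i - muj)^2 * pj))
  corr <- if (sdi * sdj < 1e-12) 1 else
    sum(outer(i - mui, i - muj) * P) / (sdi * sdj)
  c(energy = sum(P^2),
    contrast = sum(D^2 * P),
    correlation = corr,
    homogeneity = sum(P / (1 + D^2)))
}

#' GLCM texture features
#'
#' Energy (sum of squared entries), contrast, correlation (defined as 1 for a
#' degenerate zero-variance matrix: a perfectly homogeneous region is
#' perfectly predictable), and homogeneity. For a multi-offset [glcm()] the
#' features are averaged over offsets.
#'
#' @param x A [glcm()] object or a single normalized co-occurrence matrix.
#' @return Named numeric vector `(energy, contrast, correlation, homogeneity)`.
#' @export
texture_features <- function(x) {
  if (inherits(x, "glcm")) {
    K <- dim(x$p)[3L]
    feats <- vapply(seq_len(K), function(k) texture_features_one(x$p[, , k]),
                    numeric(4))
    return(rowMeans(feats))
  }
  texture_features_one(as.matrix(x))
}

#' Colour and texture profile of an annotated region
#'
#' Pixels inside the polygon (even-odd rule on pixel centres) contribute to
#' per-channel intensity means, the CIELab coordinates of the region colour,
#' and per-channel GLCM texture features.
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param annotation A [region_annotation()].
#' @param params A [glcm_params()].
#' @param per_pixel_lab If `TRUE`, CIELab is the mean of per-pixel Lab values
#'   instead of the Lab of the mean RGB (the default, which is stabler for
#'   small regions).
#' @return An object of class `region_profile`: `label`, `n_pixels`, `color`
#'   (named vector `mean_R, mean_G, mean_B, L_star, a_star, b_star`) and
#'   `texture` (list `R`, `G`, `B` of feature vectors).
#' @export
region_profiles <- function(image, annotation, params = glcm_params(),
                            per_pixel_lab = FALSE) {
  stopifnot(inherits(annotation, "region_annotation"))
  d <- dim(image)
  if (length(d) != 3L || d[3L] < 3L)
    stop("image must be an H x W x 3 array", call. = FALSE)
  mask <- polygon_mask(annotation$polygon, d[2L], d[1L])
  n <- sum(mask)
  if (n == 0L)
    stop("region error: polygon covers no pixels inside the raster", call. = FALSE)
  chans <- lapply(1:3, function(k) image[, , k])
  means <- vapply(chans, function(ch) mean(ch[mask]), numeric(1))
  lab <- if (per_pixel_lab) {
    colMeans(rgb_to_cielab(cbind(chans[[1]][mask], chans[[2]][mask],
                                 chans[[3]][mask])))
  } else {
    rgb_to_cielab(means)
  }
  texture <- lapply(chans, function(ch) texture_features(glcm(ch, params, mask)))
  names(texture) <- c("R", "G", "B")
  structure(list(label = annotation$label,
                 n_pixels = n,
                 color = c(mean_R = means[1L], mean_G = means[2L],
                           mean_B = means[3L],
                           L_star = unname(lab[1L]), a_star = unname(lab[2L]),
                           b_star = unname(lab[3L])),
                 texture = texture),
            class = "region_profile")
}

# Flatten a region_profile into a one-row data.frame (CSV schema).
profile_row <- function(profile, image_id = NA_character_) {
  tx <- profile$texture
  row <- data.frame(image = image_id, region = profile$label,
                    n_pixels = profile$n_pixels,
                    t(profile$color), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (ch in names(tx))
    for (f in names(tx[[ch]]))
      row[[paste0(f, "_", ch)]] <- unname(tx[[ch]][f])
  row
}
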