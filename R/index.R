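# The weighted function index scoring post-intubation mucosal inflammation:
# a normalized colour term plus R-channel GLCM contrast and correlation,
# squared and weighted 0.35 / 0.34 / 0.32.

#' Function index weights
#'
#' Defaults are the published coefficients of the index
#' `0.35 * color^2 + 0.34 * contrast^2 + 0.32 * correlation^2`.
#'
#' @param w_color,w_contrast,w_correlation Non-negative weights.
#' @return An object of class `index_weights`.
#' @export
index_weights <- function(w_color = 0.35, w_contrast = 0.34,
                          w_correlation = 0.32) {
  w <- c(w_color = w_color, w_contrast = w_contrast,
         w_correlation = w_correlation)
  if (any(!is.finite(w)) || any(w < 0))
    stop("config error: weights must be non-negative", call. = FALSE)
  structure(as.list(w), class = "index_weights")
}

#' Min-max normalization to \[0, 1\]
#'
#' `(v - min) / (max - min)`; a constant input maps to all zeros.
#'
#' @param values Numeric vector of length >= 2.
#' @return Numeric vector in \[0, 1\].
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 2L)
    stop("value error: need at least 2 values to normalize", call. = FALSE)
  if (any(!is.finite(values)))
    stop("value error: values must be finite", call. = FALSE)
  rng <- range(values)
  if (rng[2L] == rng[1L]) return(rep(0, length(values)))
  (values - rng[1L]) / (rng[2L] - rng[1L])
}

#' Weighted quadratic function index
#'
#' `w_color * color^2 + w_contrast * contrast^2 + w_correlation *
#' correlation^2` on normalized features. With the default weights the score
#' is bounded in \[0, 1.01\].
#'
#' @param features Length-3 vector `(color, contrast, correlation)` in
#'   \[0, 1\], or an n x 3 matrix.
#' @param weights An [index_weights()].
#' @return Numeric score(s).
#' @export
function_index <- function(features, weights = index_weights()) {
  stopifnot(inherits(weights, "index_weights"))
  m <- if (is.null(dim(features))) matrix(as.numeric(features), nrow = 1L)
       else as.matrix(features)
  if (ncol(m) != 3L)
    stop("features must have 3 components (color, contrast, correlation)",
         call. = FALSE)
  if (any(m < -1e-9) || any(m > 1 + 1e-9))
    stop("value error: normalized features must lie in [0, 1]", call. = FALSE)
  w <- c(weights$w_color, weights$w_contrast, weights$w_correlation)
  drop(m^2 %*% w)
}

# Extract the (color, contrast, correlation) scalars from one image's
# region profiles for a given region label.
extract_index_features <- function(profiles_by_region, region, channel,
                                   color_feature) {
  prof <- NULL
  if (inherits(profiles_by_region, "region_profile")) {
    if (profiles_by_region$label == region) prof <- profiles_by_region
  } else {
    for (p in profiles_by_region)
      if (inherits(p, "region_profile") && p$label == region) prof <- p
  }
  if (is.null(prof))
    stop(sprintf("region error: no '%s' profile for an image", region),
         call. = FALSE)
  c(color = unname(prof$color[color_feature]),
    contrast = unname(prof$texture[[channel]]["contrast"]),
    correlation = unname(prof$texture[[channel]]["correlation"]))
}

#' Cohort-normalized function index scores
#'
#' For each image, extracts the colour scalar (by default a*, the red-green
#' CIELab coordinate), the GLCM contrast, and the GLCM correlation of the
#' requested region (by default from the R channel, the most discriminative
#' one), min-max normalizes each feature across the cohort, and applies the
#' function index.
#'
#' @param profiles List over images; each element is either a single
#'   `region_profile` or a list of `region_profile`s covering the requested
#'   region.
#' @param region Region label to score, default `"interarytenoid"`.
#' @param weights An [index_weights()].
#' @param channel Texture channel, default `"R"`.
#' @param color_feature Colour scalar: `"a_star"` (default) or any column of
#'   the profile colour vector.
#' @return A data.frame with raw features, normalized features, and `score`.
#' @export
cohort_index <- function(profiles, region = "interarytenoid",
                         weights = index_weights(), channel = "R",
                         color_feature = "a_star") {
  if (length(profiles) < 2L)
    stop("value error: need at least 2 profiles", call. = FALSE)
  raw <- t(vapply(profiles, extract_index_features, numeric(3),
                  region = region, channel = channel,
                  color_feature = color_feature))
  norm <- apply(raw, 2L, minmax_normalize)
  score <- function_index(norm, weights)
  data.frame(color = raw[, 1L], contrast = raw[, 2L], correlation = raw[, 3L],
             color_n = norm[, 1L], contrast_n = norm[, 2L],
             correlation_n = norm[, 3L], score = score)
}
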