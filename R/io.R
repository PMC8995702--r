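# File formats: PNG/TIFF rasters in [0, 1], annotation JSON, phantom truth
# JSON, cohort manifest CSV, and the rig configuration (YAML).

#' Read an RGB image as an H x W x 3 array in \[0, 1\]
#'
#' PNG and TIFF are supported; 8- and 16-bit integer data are rescaled to
#' \[0, 1\] by the readers. Grayscale images are expanded to three channels
#' and an alpha channel is dropped.
#'
#' @param path Image file path.
#' @return Numeric array, height x width x 3.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: cannot read image '%s'", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("I/O error: unsupported image format '%s' (%s)", ext, path),
         call. = FALSE))
  if (length(dim(img)) == 2L)
    img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L)
    img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an RGB image to PNG
#' @param image H x W x 3 array in \[0, 1\].
#' @param path Output path (.png).
#' @export
write_image <- function(image, path) {
  png::writePNG(clip01(image), path)
  invisible(path)
}

#' Read region annotations from JSON
#'
#' Schema: `{image: path, regions: [{label, polygon: [[x, y], ...],
#' landmarks: {name: [x, y]}}]}`. Labels outside the fixed vocabulary,
#' polygons with fewer than 3 vertices, and malformed landmarks are
#' rejected with an error naming the offending field.
#'
#' @param path JSON file path.
#' @return List of [region_annotation()] objects; the source image path, if
#'   present, is attached as attribute `image`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: cannot read annotations '%s'", path), call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$regions) || !is.list(doc$regions))
    stop("parse error: missing 'regions' array (field: regions)", call. = FALSE)
  anns <- lapply(doc$regions, function(r) {
    if (is.null(r$label))
      stop("parse error: region without a label (field: label)", call. = FALSE)
    if (is.null(r$polygon) || length(r$polygon) < 3L)
      stop("parse error: polygon needs at least 3 vertices (field: polygon)",
           call. = FALSE)
    poly <- do.call(rbind, lapply(r$polygon, function(pt) {
      pt <- as.numeric(pt)
      if (length(pt) != 2L || anyNA(pt))
        stop("parse error: polygon vertex must be [x, y] (field: polygon)",
             call. = FALSE)
      pt
    }))
    region_annotation(r$label, poly, r$landmarks)
  })
  attr(anns, "image") <- doc$image
  anns
}

#' Write region annotations to JSON
#' @param annotations List of [region_annotation()] objects.
#' @param path Output path.
#' @param image Optional image path recorded in the file.
#' @export
write_annotations <- function(annotations, path, image = NULL) {
  doc <- list(
    image = image,
    regions = lapply(annotations, function(a) {
      out <- list(label = a$label,
                  polygon = lapply(seq_len(nrow(a$polygon)),
                                   function(i) as.numeric(a$polygon[i, ])))
      if (!is.null(a$landmarks)) out$landmarks <- a$landmarks
      out
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# Convert a phantom truth record into region annotations (+ landmarks).
truth_annotations <- function(truth) {
  anns <- lapply(names(truth$regions), function(nm) {
    lm <- if (nm == "glottis") truth$landmarks_px else NULL
    region_annotation(nm, truth$regions[[nm]], lm)
  })
  anns
}

#' Write a phantom scene to disk
#'
#' Writes `<id>.png` plus a sidecar `<id>_truth.json` holding the ground
#' truth (scale, fiducials, region polygons, landmarks, morphometry) and a
#' `<id>_annotations.json` in the standard annotation schema.
#'
#' @param scene A `phantom_scene`.
#' @param dir Output directory (created if missing).
#' @param id Scene identifier used as the file stem.
#' @return Named character vector of the written paths.
#' @export
write_scene <- function(scene, dir, id) {
  stopifnot(inherits(scene, "phantom_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(id, ".png"))
  truth_path <- file.path(dir, paste0(id, "_truth.json"))
  ann_path <- file.path(dir, paste0(id, "_annotations.json"))
  write_image(scene$image, img_path)
  tr <- scene$truth
  tr$regions <- lapply(tr$regions, function(p)
    lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ])))
  if (!is.null(tr$dot_centers_px))
    tr$dot_centers_px <- lapply(1:2, function(i) as.numeric(scene$truth$dot_centers_px[i, ]))
  if (!is.null(tr$morphometry_mm))
    tr$morphometry_mm <- as.list(unclass(tr$morphometry_mm))
  jsonlite::write_json(tr, truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  write_annotations(truth_annotations(scene$truth), ann_path,
                    image = basename(img_path))
  c(image = img_path, truth = truth_path, annotations = ann_path)
}

#' Write a phantom cohort and its manifest
#'
#' Writes every scene via [write_scene()] and a `manifest.csv` with columns
#' `scene_id, subject, label, inflammation, seed, image, annotations, truth`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory.
#' @return Path of the manifest CSV.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(cohort), function(i) {
    e <- cohort[[i]]
    id <- sprintf("scene_%03d_%s", e$subject, e$label)
    paths <- write_scene(e$scene, dir, id)
    # paths are stored relative to the manifest so the cohort is relocatable
    data.frame(scene_id = id, subject = e$subject, label = e$label,
               inflammation = e$inflammation, seed = e$scene$truth$seed,
               image = basename(paths[["image"]]),
               annotations = basename(paths[["annotations"]]),
               truth = basename(paths[["truth"]]), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  path
}

#' Rig configuration
#'
#' Bundles the laser rig constants and analysis parameters. The defaults
#' reproduce the clinical rig: 1 mm dot separation, 8.5 degree line tilt,
#' green (515 nm) laser.
#'
#' @param dot_separation_mm Laser dot / reference line separation, mm.
#' @param line_tilt_deg Tilted-line angle, degrees.
#' @param laser_channel `"R"`, `"G"`, or `"B"`.
#' @param glcm A [glcm_params()].
#' @param index_weights An [index_weights()].
#' @param index_channel Texture channel feeding the function index.
#' @param color_feature Colour scalar feeding the function index.
#' @param seed Integer seed for any stochastic stage.
#' @return An object of class `rig_config`.
#' @export
rig_config <- function(dot_separation_mm = 1.0, line_tilt_deg = 8.5,
                       laser_channel = "G", glcm = glcm_params(),
                       index_weights = NULL,
                       index_channel = "R", color_feature = "a_star",
                       seed = 1L) {
  if (is.null(index_weights)) index_weights <- laryngometry::index_weights()
  if (dot_separation_mm <= 0)
    stop("config error: dot_separation_mm must be positive", call. = FALSE)
  if (line_tilt_deg <= 0 || line_tilt_deg >= 90)
    stop("config error: line_tilt_deg must lie strictly in (0, 90)", call. = FALSE)
  if (!laser_channel %in% c("R", "G", "B"))
    stop("config error: laser_channel must be R, G, or B", call. = FALSE)
  structure(list(dot_separation_mm = dot_separation_mm,
                 line_tilt_deg = line_tilt_deg,
                 laser_channel = laser_channel,
                 glcm = glcm, index_weights = index_weights,
                 index_channel = index_channel,
                 color_feature = color_feature,
                 seed = as.integer(seed)),
            class = "rig_config")
}

#' Read a rig configuration from YAML
#' @param path YAML file; unknown keys are rejected.
#' @return A [rig_config()].
#' @export
read_rig_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("dot_separation_mm", "line_tilt_deg", "laser_channel",
             "glcm", "index_weights", "index_channel", "color_feature", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("parse error: unknown config key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (!is.null(y$glcm)) y$glcm <- do.call(glcm_params, y$glcm)
  if (!is.null(y$index_weights))
    y$index_weights <- do.call(index_weights, y$index_weights)
  do.call(rig_config, y)
}
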