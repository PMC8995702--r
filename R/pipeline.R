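#' Run the full analysis pipeline on a cohort manifest
#'
#' For every manifest row the pipeline reads the image and its annotations,
#' calibrates the metric scale from the laser dot pair, computes region
#' colour/texture profiles and the laryngeal morphometry, then pools the
#' cohort: function-index scores for the interarytenoid region (and the
#' vocal folds), ROC analysis of the scores against pre/post labels, and
#' per-subject percent-change tables of the morphometric parameters.
#'
#' Per-image failures are logged and skipped; the run fails only when more
#' than half of the images fail.
#'
#' @param manifest Path to a manifest CSV (columns `scene_id, subject,
#'   label, image, annotations`) or an equivalent data.frame. Paths are
#'   interpreted relative to the manifest's directory when not absolute.
#' @param config A [rig_config()].
#' @param out_dir Optional output directory; when given, features,
#'   morphometry, scores, percent changes, the ROC summary, and a run log
#'   (config, seed, package version) are written there.
#' @return A list bundle: `features` (data.frame), `morphometry`
#'   (data.frame), `scores` (data.frame), `roc` (a `roc_result` or `NULL`),
#'   `percent_change` (data.frame or `NULL`), `failures` (character).
#' @export
run_pipeline <- function(manifest, config = rig_config(), out_dir = NULL) {
  stopifnot(inherits(config, "rig_config"))
  base_dir <- "."
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("scene_id", "subject", "label", "image", "annotations")
  missing_cols <- setdiff(need, names(manifest))
  if (length(missing_cols))
    stop("manifest is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base_dir, p))

  feats <- list(); morphs <- list(); profiles <- list(); failures <- character(0)
  kept <- logical(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      img <- read_image(resolve(row$image))
      anns <- read_annotations(resolve(row$annotations))
      dots <- detect_laser_dots(img, channel = config$laser_channel)
      scale <- scale_from_dots(dots, config$dot_separation_mm)
      prof <- lapply(anns, function(a) {
        if (a$label == "glottis") return(NULL)  # airway gap: geometry only
        region_profiles(img, a, config$glcm)
      })
      prof <- Filter(Negate(is.null), prof)
      morph <- laryngeal_morphometry(anns, scale)
      list(prof = prof, morph = morph, scale = scale)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", row$scene_id, conditionMessage(res)))
      next
    }
    kept[i] <- TRUE
    profiles[[row$scene_id]] <- res$prof
    feats[[row$scene_id]] <- do.call(rbind, lapply(res$prof, profile_row,
                                                   image_id = row$scene_id))
    morphs[[row$scene_id]] <- data.frame(scene_id = row$scene_id,
                                         subject = row$subject,
                                         label = row$label,
                                         mm_per_px = res$scale$mm_per_px,
                                         t(unclass(res$morph)),
                                         stringsAsFactors = FALSE)
  }
  if (length(failures) > nrow(manifest) / 2)
    stop("pipeline error: more than half of the images failed:\n",
         paste(failures, collapse = "\n"), call. = FALSE)

  features <- do.call(rbind, feats)
  morphometry <- do.call(rbind, morphs)
  rownames(features) <- rownames(morphometry) <- NULL
  man_kept <- manifest[kept, ]

  scores <- NULL; roc <- NULL
  have_regions <- unique(features$region)
  if ("interarytenoid" %in% have_regions && nrow(man_kept) >= 2L) {
    idx <- cohort_index(profiles, region = "interarytenoid",
                        weights = config$index_weights,
                        channel = config$index_channel,
                        color_feature = config$color_feature)
    scores <- cbind(data.frame(scene_id = man_kept$scene_id,
                               subject = man_kept$subject,
                               label = man_kept$label,
                               stringsAsFactors = FALSE), idx)
    if (length(unique(man_kept$label)) == 2L)
      roc <- roc_analysis(scores$score, scores$label)
  }

  pct <- NULL
  if (!is.null(morphometry) && all(c("pre", "post") %in% morphometry$label)) {
    pre <- morphometry[morphometry$label == "pre", ]
    post <- morphometry[morphometry$label == "post", ]
    common <- intersect(pre$subject, post$subject)
    if (length(common)) {
      rows <- lapply(common, function(s) {
        p0 <- pre[match(s, pre$subject), morphometry_fields]
        p1 <- post[match(s, post$subject), morphometry_fields]
        ok <- !is.na(p0) & !is.na(p1) & p0 > 0
        out <- stats::setNames(rep(NA_real_, length(morphometry_fields)),
                               morphometry_fields)
        out[as.logical(ok)] <- 100 * as.numeric(p1[as.logical(ok)]) /
          as.numeric(p0[as.logical(ok)])
        data.frame(subject = s, t(out), stringsAsFactors = FALSE)
      })
      pct <- do.call(rbind, rows)
    }
  }

  bundle <- list(features = features, morphometry = morphometry,
                 scores = scores, roc = roc, percent_change = pct,
                 failures = failures)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(morphometry, file.path(out_dir, "morphometry.csv"),
                     row.names = FALSE)
    if (!is.null(scores))
      utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                       row.names = FALSE)
    if (!is.null(pct))
      utils::write.csv(pct, file.path(out_dir, "percent_change.csv"),
                       row.names = FALSE)
    if (!is.null(roc))
      jsonlite::write_json(list(auc = roc$auc, cutoff = roc$cutoff,
                                sensitivity = roc$sensitivity,
                                specificity = roc$specificity,
                                accuracy = roc$accuracy),
                           file.path(out_dir, "roc.json"),
                           auto_unbox = TRUE, digits = NA)
    log <- list(timestamp = format(Sys.time(), tz = "UTC"),
                package_version = as.character(utils::packageVersion("laryngometry")),
                r_version = R.version.string,
                seed = config$seed,
                config = config_as_list(config),
                n_images = nrow(manifest),
                n_failed = length(failures),
                failures = failures)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  bundle
}

# Serialize a rig_config (and nested parameter objects) for the run log.
config_as_list <- function(config) {
  out <- unclass(config)
  out$glcm <- unclass(out$glcm)
  out$glcm$offsets <- lapply(seq_len(nrow(out$glcm$offsets)),
                             function(i) as.integer(out$glcm$offsets[i, ]))
  out$index_weights <- unclass(out$index_weights)
  out
}
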