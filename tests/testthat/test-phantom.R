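test_that("identical config and seed give a bit-identical scene", {
  cfg <- phantom_config(seed = 42L, inflammation = 0.4)
  s1 <- generate_laryngeal_scene(cfg)
  s2 <- generate_laryngeal_scene(cfg)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth, s2$truth)
  o1 <- generate_oropharyngeal_scene(cfg)
  o2 <- generate_oropharyngeal_scene(cfg)
  expect_identical(o1$image, o2$image)
})

test_that("truth record encodes the configured scale and dot geometry", {
  cfg <- phantom_config(mm_per_px_true = 0.05, dot_separation_mm = 1.0)
  sc <- generate_laryngeal_scene(cfg)
  expect_equal(sc$truth$mm_per_px, 0.05)
  d <- sc$truth$dot_centers_px
  expect_equal(sqrt(sum((d[1, ] - d[2, ])^2)), 20.0)
  # every truth polygon lies inside the raster
  for (p in sc$truth$regions) {
    expect_true(all(p[, 1] >= 0 & p[, 1] <= cfg$image_width - 1))
    expect_true(all(p[, 2] >= 0 & p[, 2] <= cfg$image_height - 1))
  }
})

test_that("rendered fiducials agree with truth centres within 0.5 px", {
  for (seed in c(3L, 9L)) {
    sc <- generate_laryngeal_scene(phantom_config(seed = seed))
    found <- detect_laser_dots(sc$image)
    expect_lt(max(abs(found - sc$truth$dot_centers_px)), 0.5)
  }
})

test_that("interarytenoid redness and local variance increase with inflammation", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  red <- var_r <- numeric(length(grid))
  for (i in seq_along(grid)) {
    sc <- generate_laryngeal_scene(phantom_config(inflammation = grid[i],
                                                  seed = 11L))
    m <- polygon_mask(sc$truth$regions$interarytenoid,
                      ncol(sc$image[, , 1]), nrow(sc$image[, , 1]))
    px <- sc$image[, , 1][m]
    red[i] <- mean(px)
    var_r[i] <- stats::var(px)
  }
  expect_true(all(diff(red) > 0))
  expect_true(all(diff(var_r) > 0))
})

test_that("fold region redness also increases, but less than interarytenoid", {
  s0 <- generate_laryngeal_scene(phantom_config(inflammation = 0, seed = 5L))
  s1 <- generate_laryngeal_scene(phantom_config(inflammation = 1, seed = 5L))
  mean_region <- function(sc, region) {
    m <- polygon_mask(sc$truth$regions[[region]], dim(sc$image)[2], dim(sc$image)[1])
    mean(sc$image[, , 1][m])
  }
  d_ia <- mean_region(s1, "interarytenoid") - mean_region(s0, "interarytenoid")
  d_vf <- mean_region(s1, "vocal_fold_left") - mean_region(s0, "vocal_fold_left")
  expect_gt(d_ia, 0)
  expect_gt(d_vf, 0)
  expect_gt(d_ia, d_vf)
})

test_that("oropharyngeal tilted-line displacement follows depth * tan(theta)", {
  # zero depth: no displacement between surfaces
  s0 <- generate_oropharyngeal_scene(phantom_config(depth_offset_mm = 0))
  expect_equal(s0$truth$shift_px, 0)
  # 10 mm at 8.5 degrees -> 1.494 mm of lateral shift
  s10 <- generate_oropharyngeal_scene(phantom_config(depth_offset_mm = 10))
  expect_equal(s10$truth$shift_px * s10$truth$mm_per_px,
               10 * tan(8.5 * pi / 180))
  expect_equal(s10$truth$shift_px * s10$truth$mm_per_px, 1.494,
               tolerance = 1e-3)
  # 45 degrees, 5 mm deep -> exactly 5 mm of shift
  s45 <- generate_oropharyngeal_scene(
    phantom_config(depth_offset_mm = 5, line_tilt_deg = 45))
  expect_equal(s45$truth$shift_px * s45$truth$mm_per_px, 5.0)
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(image_width = 0), "config error")
  expect_error(phantom_config(inflammation = 1.5), "config error")
  expect_error(phantom_config(noise_sd = -1), "config error")
  expect_error(phantom_config(line_tilt_deg = 0), "config error")
  expect_error(phantom_config(line_tilt_deg = 95), "config error")
  expect_error(
    phantom_config(glottis_polygon_mm = rbind(c(0, 0), c(1, 0), c(2, 0))),
    "collinear")
  # polygon outside the raster (field of view is 24 x 18 mm by default)
  big <- rbind(c(-5, 5), c(40, 5), c(40, 12), c(-5, 12))
  expect_error(
    generate_laryngeal_scene(phantom_config(glottis_polygon_mm = big)),
    "geometry error")
})

test_that("cohort generation is paired, labelled, and deterministic", {
  co <- generate_cohort(1, seed = 7L)
  expect_length(co, 2L)
  expect_setequal(vapply(co, `[[`, character(1), "label"), c("pre", "post"))

  co2 <- generate_cohort(3, seed = 99L)
  expect_length(co2, 6L)
  infl <- vapply(co2, `[[`, numeric(1), "inflammation")
  expect_true(all(infl >= 0 & infl <= 1))
  labs <- vapply(co2, `[[`, character(1), "label")
  # post scenes drawn around the higher mean
  expect_gt(mean(infl[labs == "post"]), mean(infl[labs == "pre"]))
  co3 <- generate_cohort(3, seed = 99L)
  expect_identical(co2[[2]]$scene$image, co3[[2]]$scene$image)

  # zero class separation: both classes drawn from the same distribution
  null_eff <- inflammation_effect(pre_mean = 0.4, post_mean = 0.4, sd = 0.1)
  co4 <- generate_cohort(4, effect = null_eff, seed = 1L)
  i4 <- vapply(co4, `[[`, numeric(1), "inflammation")
  expect_true(all(i4 >= 0 & i4 <= 1))
  expect_error(generate_cohort(0), "n_per_class")
})
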