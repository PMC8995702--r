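test_that("calibrated polygon area: unit square, rotation, and raster oracle", {
  sq <- rbind(c(0, 0), c(20, 0), c(20, 20), c(0, 20))
  expect_equal(polygon_area_mm2(sq, 0.05), 1.0)
  rot <- laryngometry:::rotate_points(sq, 37, center = c(10, 10))
  expect_equal(polygon_area_mm2(rot, 0.05), 1.0, tolerance = 1e-9)

  set.seed(12)
  for (rep in 1:5) {
    poly <- random_convex_polygon(7)
    a_shoelace <- polygon_area_mm2(poly, 1)
    a_raster <- area_oracle_px2(poly)
    expect_lt(abs(a_shoelace - a_raster) / a_raster, 0.02)
  }

  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(polygon_area_mm2(bowtie, 1), "self-intersecting")
  expect_error(polygon_area_mm2(rbind(c(0, 0), c(1, 1)), 1), "3 vertices")
})

test_that("fold metrics on an axis-aligned and rotated rectangle", {
  rect <- rbind(c(0, 0), c(100, 0), c(100, 20), c(0, 20))
  m <- vocal_fold_metrics(rect, 0.05)
  expect_equal(unname(m["length_mm"]), 5.0)
  expect_equal(unname(m["width_mm"]), 1.0)
  expect_equal(unname(m["area_mm2"]), 5.0)

  for (ang in c(13, 45, 78, 122)) {
    r <- laryngometry:::rotate_points(rect, ang, center = c(50, 10))
    mr <- vocal_fold_metrics(r, 0.05)
    expect_equal(unname(mr["length_mm"]), 5.0, tolerance = 0.01)
    expect_equal(unname(mr["width_mm"]), 1.0, tolerance = 0.01)
    expect_equal(unname(mr["area_mm2"]), 5.0, tolerance = 1e-9)
  }
  expect_error(vocal_fold_metrics(rbind(c(0, 0), c(1e-9, 0), c(0, 1e-9)), 1),
               "geometry error")
})

test_that("fold metrics recover phantom truth through the full chain", {
  cfg <- phantom_config(fold_length_mm = 9, fold_width_mm = 3,
                        fold_angle_deg = 24, seed = 6L)
  sc <- generate_laryngeal_scene(cfg)
  scale <- scale_from_dots(detect_laser_dots(sc$image), cfg$dot_separation_mm)
  m <- vocal_fold_metrics(sc$truth$regions$vocal_fold_left, scale)
  expect_lt(abs(m["length_mm"] - 9) / 9, 0.05)
  expect_lt(abs(m["width_mm"] - 3) / 3, 0.05)
  expect_lt(abs(m["area_mm2"] - 27) / 27, 0.05)
})

test_that("vocal angle from landmarks", {
  ac <- c(0, 0)
  expect_equal(vocal_angle(ac, c(-sin(10 * pi / 180), cos(10 * pi / 180)),
                           c(sin(10 * pi / 180), cos(10 * pi / 180))), 20)
  expect_equal(vocal_angle(ac, c(-1, 0), c(1, 0)), 180)
  expect_equal(vocal_angle(c(0, 0), c(1, 0), c(0, 1)), 90)
  expect_error(vocal_angle(c(0, 0), c(0, 0), c(1, 1)), "geometry error")
})

test_that("aggregate_max takes field-wise maxima over evaluations", {
  e1 <- morphometry_result(glottic_area_mm2 = 80, vocal_length_left_mm = 12)
  e2 <- morphometry_result(glottic_area_mm2 = 95, vocal_length_left_mm = 10)
  e3 <- morphometry_result(glottic_area_mm2 = 90, vocal_length_left_mm = 11)
  agg <- aggregate_max(list(e1, e2, e3))
  expect_equal(unname(agg["glottic_area_mm2"]), 95)
  # maxima of different fields may come from different evaluations
  expect_equal(unname(agg["vocal_length_left_mm"]), 12)
  # identity, idempotence, permutation invariance
  expect_equal(aggregate_max(list(e1)), e1)
  expect_equal(aggregate_max(list(agg, agg)), agg)
  expect_equal(aggregate_max(list(e3, e1, e2)), agg)
  # aggregate dominates every evaluation field-wise
  for (e in list(e1, e2, e3))
    expect_true(all(agg >= e, na.rm = TRUE))
  expect_error(aggregate_max(list()), "value error")
})

test_that("percent change follows the pre = 100% convention", {
  expect_equal(percent_change(100, 100), 100)
  expect_equal(percent_change(10, 5), 50)
  expect_equal(percent_change(10, 5, signed = TRUE), -50)
  # printed fold widths: 2.96 -> 3.61 mm is a 21.96% increase
  expect_equal(percent_change(2.96, 3.61, signed = TRUE), 21.96,
               tolerance = 1e-3)
  expect_error(percent_change(0, 5), "value error")
  expect_error(percent_change(-2, 5), "value error")
})

test_that("metrics are invariant to rigid motion and linear in the scale", {
  rect <- rbind(c(10, 5), c(90, 5), c(90, 25), c(10, 25))
  m0 <- vocal_fold_metrics(rect, 0.05)
  shifted <- sweep(rect, 2, c(31.7, -12.2), `+`)
  expect_equal(vocal_fold_metrics(shifted, 0.05), m0, tolerance = 1e-9)
  rot <- laryngometry:::rotate_points(shifted, 61, center = c(0, 0))
  expect_equal(vocal_fold_metrics(rot, 0.05), m0, tolerance = 0.01)

  k <- 3
  mk <- vocal_fold_metrics(rect, 0.05 * k)
  expect_equal(unname(mk["length_mm"]), unname(m0["length_mm"]) * k)
  expect_equal(unname(mk["width_mm"]), unname(m0["width_mm"]) * k)
  expect_equal(unname(mk["area_mm2"]), unname(m0["area_mm2"]) * k^2)
})

test_that("laryngeal morphometry assembles the parameter set from annotations", {
  sc <- generate_laryngeal_scene(phantom_config(seed = 44L))
  anns <- c(
    lapply(c("vocal_fold_left", "vocal_fold_right", "glottis"), function(nm)
      region_annotation(nm, sc$truth$regions[[nm]],
                        if (nm == "glottis") sc$truth$landmarks_px else NULL)))
  m <- laryngeal_morphometry(anns, sc$truth$mm_per_px)
  truth <- sc$truth$morphometry_mm
  for (f in c("vocal_length_left_mm", "vocal_width_right_mm",
              "glottic_area_mm2", "vocal_angle_deg"))
    expect_equal(unname(m[f]), unname(truth[f]), tolerance = 0.02)
  expect_true(is.na(m["csaoi_mm2"]))
})
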