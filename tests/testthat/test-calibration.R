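make_blob_image <- function(centers, amps, size = c(120, 160), sigma = 2) {
  img <- array(0.2, c(size[1], size[2], 3))
  X <- matrix(0:(size[2] - 1), size[1], size[2], byrow = TRUE)
  Y <- matrix(0:(size[1] - 1), size[1], size[2])
  for (i in seq_len(nrow(centers))) {
    m <- amps[i] * exp(-((X - centers[i, 1])^2 + (Y - centers[i, 2])^2) /
                         (2 * sigma^2))
    img[, , 2] <- img[, , 2] + m
  }
  img[, , 2] <- pmin(img[, , 2], 1)
  img
}

test_that("dot detection is sub-pixel accurate on phantoms and picks the brightest pair", {
  sc <- generate_laryngeal_scene(phantom_config(seed = 21L))
  d <- detect_laser_dots(sc$image)
  expect_lt(max(abs(d - sc$truth$dot_centers_px)), 0.5)
  expect_true(attr(d, "quality") > 0 && attr(d, "quality") <= 1)
  # dots ordered by x then y
  expect_true(d[1, 1] <= d[2, 1])

  # three blobs, one dim: the two brightest are returned
  img <- make_blob_image(rbind(c(40.5, 60.5), c(100.25, 30.75), c(70, 90)),
                         amps = c(0.8, 0.75, 0.3))
  d3 <- detect_laser_dots(img)
  expect_equal(sort(d3[, 1]), c(40.5, 100.25), tolerance = 0.5)

  # blank image: no fiducials
  blank <- array(0.3, c(50, 50, 3))
  expect_error(detect_laser_dots(blank), "detection error")
})

test_that("scale_from_dots implements separation / pixel distance", {
  s <- scale_from_dots(rbind(c(0, 0), c(20, 0)), 1.0)
  expect_equal(s$mm_per_px, 0.05)
  s2 <- scale_from_dots(rbind(c(10, 10), c(10, 35)), 1.0)
  expect_equal(s2$mm_per_px, 0.04)
  expect_error(scale_from_dots(rbind(c(5, 5), c(5, 5)), 1.0), "coincident")
  expect_error(scale_from_dots(rbind(c(0, 0), c(1, 0)), 0), "positive")
})

test_that("recovered scale matches phantom truth within 1%", {
  sc <- generate_laryngeal_scene(phantom_config(mm_per_px_true = 0.08,
                                                seed = 4L))
  s <- scale_from_dots(detect_laser_dots(sc$image), 1.0)
  expect_lt(abs(s$mm_per_px - 0.08) / 0.08, 0.01)
})

test_that("scale is invariant to 90-degree rotation and scales with downsampling", {
  sc <- generate_laryngeal_scene(phantom_config(seed = 13L))
  s0 <- scale_from_dots(detect_laser_dots(sc$image), 1.0)$mm_per_px
  H <- dim(sc$image)[1]
  rot <- aperm(sc$image[H:1, , , drop = FALSE], c(2, 1, 3))
  s90 <- scale_from_dots(detect_laser_dots(rot), 1.0)$mm_per_px
  expect_lt(abs(s90 - s0) / s0, 0.01)

  # 2x2 block-mean downsampling doubles mm per pixel
  ds <- function(img, f = 2L) {
    h <- floor(dim(img)[1] / f) * f; w <- floor(dim(img)[2] / f) * f
    out <- array(0, c(h / f, w / f, 3))
    for (k in 1:3) {
      m <- img[1:h, 1:w, k]
      m <- (m[seq(1, h, 2), ] + m[seq(2, h, 2), ]) / 2
      out[, , k] <- (m[, seq(1, w, 2)] + m[, seq(2, w, 2)]) / 2
    }
    out
  }
  s2 <- scale_from_dots(detect_laser_dots(ds(sc$image)), 1.0)$mm_per_px
  expect_lt(abs(s2 - 2 * s0) / (2 * s0), 0.02)
})

test_that("three-line detection recovers orientations within 1 degree", {
  sc <- generate_oropharyngeal_scene(phantom_config(depth_offset_mm = 0,
                                                    seed = 8L))
  ls <- detect_laser_lines(sc$image)
  # reference lines are vertical in the phantom
  for (l in ls$reference) {
    ang <- atan2(l$dir[2], l$dir[1]) * 180 / pi
    expect_lt(abs(abs(ang) - 90), 1)
  }
  expect_equal(ls$measured_tilt_deg, 8.5, tolerance = 1)
  expect_equal(ls$tilt_deg, 8.5)

  # two lines only -> detection error
  img2 <- array(0.3, c(80, 120, 3))
  img2[, 30, 2] <- 1; img2[, 31, 2] <- 1
  img2[, 70, 2] <- 1; img2[, 71, 2] <- 1
  expect_error(detect_laser_lines(img2), "detection error")
})

test_that("depth follows the tangent relation", {
  d0 <- depth_from_line_offset(8.5, 3.2, 3.2)
  expect_equal(d0$depth_mm, 0)
  d1 <- depth_from_line_offset(8.5, 0, 10 * tan(8.5 * pi / 180))
  expect_equal(d1$depth_mm, 10)
  expect_equal(depth_from_line_offset(8.5, 0, 1.494)$depth_mm, 10,
               tolerance = 1e-3)
  d45 <- depth_from_line_offset(45, 1, 6)
  expect_equal(d45$depth_mm, 5.0)
  # sign preserved
  expect_lt(depth_from_line_offset(45, 6, 1)$depth_mm, 0)
  expect_error(depth_from_line_offset(8.5, NaN, 1), "value error")
  expect_error(depth_from_line_offset(0, 0, 1), "tilt")
})

test_that("scene depth round trip recovers truth within 5% over [2, 30] mm", {
  for (dep in c(2, 7, 15, 30)) {
    sc <- generate_oropharyngeal_scene(phantom_config(depth_offset_mm = dep,
                                                      seed = 17L))
    r <- depth_from_scene(sc$image, sc$truth$split_row)
    expect_lt(abs(r$depth$depth_mm - dep) / dep, 0.05)
    expect_lt(abs(r$scale$mm_per_px - sc$truth$mm_per_px) /
                sc$truth$mm_per_px, 0.01)
  }
})
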