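test_that("CIELab anchors: white, black, and the neutral axis", {
  expect_equal(unname(rgb_to_cielab(c(1, 1, 1))), c(100, 0, 0),
               tolerance = 1e-6)
  expect_equal(unname(rgb_to_cielab(c(0, 0, 0))), c(0, 0, 0),
               tolerance = 1e-6)
  g <- seq(0, 1, by = 0.01)
  lab <- rgb_to_cielab(cbind(g, g, g))
  expect_lt(max(abs(lab[, c("a_star", "b_star")])), 1e-6)
  expect_true(all(diff(lab[, "L_star"]) > 0))
  expect_true(all(lab[, "L_star"] >= 0 & lab[, "L_star"] <= 100))
  expect_error(rgb_to_cielab(c(1.2, 0, 0)), "value error")
})

test_that("CIELab agrees with an independent reference implementation", {
  set.seed(2)
  m <- matrix(runif(60), ncol = 3)
  ref <- grDevices::convertColor(m, "sRGB", "Lab")
  expect_equal(unname(rgb_to_cielab(m)), unname(ref), tolerance = 0.5)
})

test_that("worked 2x2 GLCM example matches hand enumeration", {
  img <- rbind(c(0, 0), c(1, 1))
  g <- glcm(img, glcm_params(levels = 2, offsets = rbind(c(0L, 1L))))
  P <- g$p[, , 1]
  # the two horizontal pairs are (0,0) and (1,1)
  expect_equal(P, rbind(c(0.5, 0), c(0, 0.5)))
  f <- texture_features(g)
  expect_equal(unname(f["energy"]), 0.5)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["homogeneity"]), 1)
  expect_equal(unname(f["correlation"]), 1)
})

test_that("degenerate and uniform co-occurrence matrices", {
  g <- glcm(matrix(0.4, 5, 5), glcm_params(levels = 4))
  for (k in 1:4) {
    P <- g$p[, , k]
    expect_equal(sum(P), 1)
    expect_equal(P[2, 2], 1)  # 0.4 quantized to bin 2 of 4 over [0, 1]
  }
  f <- texture_features(g)
  expect_equal(unname(f), c(1, 0, 1, 1), tolerance = 1e-12)

  L <- 4
  U <- matrix(1 / L^2, L, L)
  expect_equal(unname(texture_features(U)["energy"]), 1 / L^2)
})

test_that("GLCM and features match the brute-force oracle on random images", {
  set.seed(7)
  params <- glcm_params()
  for (rep in 1:30) {
    h <- sample(2:16, 1); w <- sample(2:16, 1)
    lv <- sample(2:8, 1)
    img <- matrix(runif(h * w), h, w)
    p <- glcm_params(levels = lv)
    g <- glcm(img, p)
    o <- glcm_oracle(img, lv, p$offsets)
    expect_equal(g$p, o, tolerance = 1e-12)
    for (k in 1:dim(o)[3])
      expect_equal(texture_features(g$p[, , k]), features_oracle(o[, , k]),
                   tolerance = 1e-12)
  }
})

test_that("masked GLCM counts only pairs fully inside the region", {
  set.seed(8)
  img <- matrix(runif(100), 10, 10)
  mask <- matrix(FALSE, 10, 10)
  mask[3:8, 2:9] <- TRUE
  mask[5, 5] <- FALSE
  p <- glcm_params(levels = 4)
  g <- glcm(img, p, mask)
  o <- glcm_oracle(img, 4, p$offsets, mask = mask)
  expect_equal(g$p, o, tolerance = 1e-12)
})

test_that("feature ranges hold on random normalized matrices", {
  set.seed(9)
  for (rep in 1:1000) {
    L <- sample(2:8, 1)
    P <- matrix(stats::rexp(L * L), L, L)
    P <- P / sum(P)
    f <- texture_features(P)
    expect_true(f["energy"] > 0 && f["energy"] <= 1)
    expect_true(f["homogeneity"] > 0 && f["homogeneity"] <= 1)
    expect_gte(unname(f["contrast"]), 0)
    expect_true(f["correlation"] >= -1 - 1e-12 && f["correlation"] <= 1 + 1e-12)
    # contrast is invariant under transposition
    expect_equal(unname(texture_features(t(P))["contrast"]),
                 unname(f["contrast"]), tolerance = 1e-12)
  }
})

test_that("invalid GLCM inputs are rejected", {
  expect_error(texture_features(matrix(c(0.5, 0.5, 0.5, 0.5), 2)),
               "value error")
  expect_error(glcm(matrix(1, 1, 1)), "region error")
  expect_error(glcm_params(levels = 1), "levels")
  expect_error(glcm_params(offsets = rbind(c(0L, 0L))), "offsets")
})

test_that("region profiles report colour means, CIELab, and texture", {
  img <- array(0, c(20, 20, 3))
  img[, , 1] <- 1  # pure red
  ann <- region_annotation("interarytenoid",
                           rbind(c(2, 2), c(15, 2), c(15, 15), c(2, 15)))
  pr <- region_profiles(img, ann)
  expect_equal(unname(pr$color["mean_R"]), 1)
  expect_equal(unname(pr$color["mean_G"]), 0)
  expect_equal(unname(pr$color["mean_B"]), 0)
  expect_gt(pr$color["a_star"], 0)  # red chromaticity
  expect_equal(pr$n_pixels, 13L * 13L)  # half-open even-odd membership

  # brighter rendering of the same region -> larger L*
  dim_img <- array(0.3, c(20, 20, 3))
  bright <- array(0.7, c(20, 20, 3))
  expect_gt(region_profiles(bright, ann)$color["L_star"],
            region_profiles(dim_img, ann)$color["L_star"])

  out <- region_annotation("glottis",
                           rbind(c(100, 100), c(120, 100), c(110, 120)))
  expect_error(region_profiles(img, out), "region error")
})

test_that("phantom interarytenoid R-channel contrast rises with inflammation", {
  prof_at <- function(i) {
    sc <- generate_laryngeal_scene(phantom_config(inflammation = i, seed = 31L))
    ann <- region_annotation("interarytenoid",
                             sc$truth$regions$interarytenoid)
    region_profiles(sc$image, ann)
  }
  p0 <- prof_at(0); p1 <- prof_at(1)
  expect_gt(p1$texture$R["contrast"], p0$texture$R["contrast"])
  expect_gt(p1$color["a_star"], p0$color["a_star"])
})
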