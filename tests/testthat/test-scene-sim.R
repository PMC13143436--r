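test_that("particle fields follow the Poisson density and are reproducible", {
  counts <- vapply(1:30, function(s)
    nrow(make_particle_field(s, 50, 19)$positions_mm), 0)
  expected <- 50 * pi * 9.5^2
  expect_lt(abs(mean(counts) - expected),
            4 * sqrt(expected) / sqrt(length(counts)))
  f1 <- make_particle_field(7, 20, 19)
  f2 <- make_particle_field(7, 20, 19)
  expect_identical(f1$positions_mm, f2$positions_mm)
  expect_identical(f1$intensities, f2$intensities)
  # different seeds give essentially disjoint position sets
  g <- make_particle_field(8, 20, 19)
  k1 <- apply(round(f1$positions_mm, 6), 1, paste, collapse = ",")
  k2 <- apply(round(g$positions_mm, 6), 1, paste, collapse = ",")
  expect_gt(mean(!k1 %in% k2), 0.99)
  expect_error(make_particle_field(1, -5), "invalid-argument")
  expect_error(make_particle_field(1, 10, layer_diameter_mm = 0),
               "invalid-argument")
})

test_that("particle field generation does not disturb the global RNG stream", {
  set.seed(42)
  a <- runif(1)
  set.seed(42)
  invisible(make_particle_field(3, 10))
  expect_identical(runif(1), a)
})

test_that("rendered particle disparities obey the stereoscopy relation", {
  rig <- test_rig()
  # a handful of well-separated particles
  pos <- cbind(c(-2.5, 0, 2, 4.3, 1.2), c(-1.5, 0.8, -0.4, 1.9, 2.6))
  field <- structure(list(positions_mm = sweep(pos, 2, c(rig$baseline_mm / 2, 0),
                                               "+"),
                          intensities = rep(0.9, nrow(pos)),
                          layer_diameter_mm = 19,
                          center_mm = c(rig$baseline_mm / 2, 0), seed = 1L),
                     class = "sop_particle_field")
  for (thick in c(1, 3)) {
    z <- rig$z_contact_mm + thick
    d <- flat_depth_field(rig, thick)
    pair <- render_stereo_pair(field, d, rig, noise_model = NULL,
                               bit_depth = 16)
    centroid <- function(img, x0, y0) {
      ix <- round(x0) + (-8:8); iy <- round(y0) + (-8:8)
      w <- img[iy, ix]
      c(sum(w %*% ix) / sum(w), sum(iy %*% w) / sum(w))
    }
    pl <- project_points(rig, field$positions_mm[, 1], field$positions_mm[, 2],
                         z, "left")
    pr <- project_points(rig, field$positions_mm[, 1], field$positions_mm[, 2],
                         z, "right")
    for (k in seq_len(nrow(pos))) {
      cl <- centroid(pair$left, pl$x[k], pl$y[k])
      cr <- centroid(pair$right, pr$x[k], pr$y[k])
      expect_lt(abs((cl[1] - cr[1]) - rig$baseline_mm * rig$focal_px / z),
                0.05)
    }
  }
})

test_that("doubling the depth halves the disparity and scales spacing as f/z", {
  rig <- test_rig()
  z1 <- 60; z2 <- 120
  expect_equal(rig$baseline_mm * rig$focal_px / z2,
               (rig$baseline_mm * rig$focal_px / z1) / 2)
  # lateral pixel spacing of two points scales as f/z
  p1 <- project_points(rig, c(2, 4), c(0, 0), z1, "left")
  p2 <- project_points(rig, c(2, 4), c(0, 0), z2, "left")
  expect_equal(diff(p1$x) / diff(p2$x), z2 / z1)
})

test_that("rendering is deterministic and respects bit depth and noise seed", {
  rig <- test_rig()
  field <- test_field()
  d <- flat_depth_field(rig, 2)
  p1 <- render_stereo_pair(field, d, rig, noise_model = render_noise(seed = 5))
  p2 <- render_stereo_pair(field, d, rig, noise_model = render_noise(seed = 5))
  expect_identical(p1$left, p2$left)
  expect_true(all(p1$left >= 0 & p1$left <= 1))
  # 8-bit quantization: values on the 1/255 grid
  expect_true(all(abs(p1$left * 255 - round(p1$left * 255)) < 1e-9))
  p3 <- render_stereo_pair(field, d, rig, noise_model = render_noise(seed = 6))
  expect_false(identical(p1$left, p3$left))
})

test_that("invalid depth geometry is rejected", {
  expect_error(depth_field(0:2, 0:1, matrix(c(1, 1, 1, 1, -1, 1), 2, 3)),
               "invalid-geometry")
  rig <- test_rig()
  small <- depth_field(c(-0.2, 0.2), c(-0.2, 0.2), matrix(100, 2, 2))
  expect_error(render_stereo_pair(test_field(), small, rig),
               "does not cover")
})

test_that("calibration stacks are monotone in thickness and validated", {
  rig <- test_rig()
  field <- test_field()
  stack <- make_calibration_stack(rig, field, 0:4, noise_model = NULL)
  expect_length(stack, 5)
  cfg <- test_match_cfg()
  md <- vapply(stack, function(s) {
    m <- match_disparity(s$pair, cfg, center = pred_disp(rig, s$thickness_mm),
                         roi = c(150L, 250L, 100L, 150L))
    mean(m$disparity[m$valid])
  }, 0)
  expect_true(all(diff(md) < 0))  # disparity strictly decreases with thickness
  expect_error(make_calibration_stack(rig, field, 2),
               "calibration-impossible")
  expect_error(make_calibration_stack(rig, field, c(1, 1, 2)),
               "invalid-argument")
})
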