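test_that("per-pixel fits recover a linear ground truth exactly", {
  th <- c(0, 1, 2, 3, 4)
  slope <- matrix(seq(-1.2, -0.8, length.out = 12), 3, 4)
  icpt <- matrix(seq(120, 130, length.out = 12), 3, 4)
  stack <- lapply(th, function(t)
    list(thickness_mm = t, map = fake_disparity_map(icpt + slope * t)))
  cal <- fit_disparity_thickness(stack)
  expect_length(cal$thicknesses_mm, 5)
  expect_equal(cal$slope_px_per_mm, slope, tolerance = 1e-12)
  expect_equal(cal$intercept_px, icpt, tolerance = 1e-12)
  expect_true(all(cal$residual_rms_px < 1e-10))
  # masked pixel in any stack entry propagates to an invalid fit
  v <- matrix(TRUE, 3, 4); v[2, 2] <- FALSE
  stack[[3]]$map <- fake_disparity_map(icpt + slope * 2, valid = v)
  cal2 <- fit_disparity_thickness(stack)
  expect_false(cal2$valid[2, 2])
  expect_true(is.na(cal2$slope_px_per_mm[2, 2]))
  expect_error(fit_disparity_thickness(stack[1]), "calibration-impossible")
})

test_that("slope noise matches the closed-form least-squares variance", {
  th <- 0:4
  sxx <- sum((th - mean(th))^2)
  sd_theory <- sqrt(0.2^2 / sxx)
  set.seed(99)
  slopes <- unlist(lapply(1:100, function(s) {
    stack <- lapply(th, function(t)
      list(thickness_mm = t,
           map = fake_disparity_map(matrix(100 - 1.1 * t +
                                             rnorm(36, 0, 0.2), 6, 6))))
    fit_disparity_thickness(stack)$slope_px_per_mm
  }))
  expect_lt(abs(mean(slopes) + 1.1), 0.01)
  expect_lt(abs(sd(slopes) / sd_theory - 1), 0.1)
})

test_that("thickness inversion round-trips and propagates masks", {
  slope <- matrix(-1.05, 4, 5)
  icpt <- matrix(124, 4, 5)
  th <- c(0, 1, 2, 3, 4)
  stack <- lapply(th, function(t)
    list(thickness_mm = t, map = fake_disparity_map(icpt + slope * t)))
  cal <- fit_disparity_thickness(stack)
  # disparity equal to the fit evaluated at 2.5 mm maps back to 2.5 mm
  dm <- fake_disparity_map(icpt + slope * 2.5)
  tm <- thickness_from_disparity(cal, dm)
  expect_equal(tm$thickness_mm, matrix(2.5, 4, 5), tolerance = 1e-12)
  # masked disparity pixel -> masked thickness pixel
  v <- matrix(TRUE, 4, 5); v[1, 3] <- FALSE
  tm2 <- thickness_from_disparity(cal, fake_disparity_map(icpt, valid = v))
  expect_false(tm2$valid[1, 3])
  expect_true(is.na(tm2$thickness_mm[1, 3]))
  # out-of-range pixels are flagged, not silently clamped
  tm3 <- thickness_from_disparity(cal, fake_disparity_map(icpt + slope * 7))
  expect_true(all(tm3$flagged))
  expect_false(any(tm3$valid))
  # zero slope at a pixel invalidates it
  cal0 <- cal
  cal0$slope_px_per_mm[2, 2] <- 0
  tm4 <- thickness_from_disparity(cal0, dm)
  expect_false(tm4$valid[2, 2])
})

test_that("a rendered noiseless stack round-trips within 0.02 mm", {
  cal <- rendered_calibration()
  # the left edge of the region maps outside the right frame and is masked
  expect_gt(mean(cal$valid), 0.85)
  expect_true(all(cal$slope_px_per_mm[cal$valid] < 0))  # one sign across pixels
  rig <- test_rig()
  field <- test_field()
  cfg <- test_match_cfg()
  for (t in c(0, 2, 4)) {
    pair <- render_stereo_pair(field, flat_depth_field(rig, t), rig,
                               noise_model = NULL)
    dm <- match_disparity(pair, cfg, center = pred_disp(rig, t),
                          roi = test_roi)
    tm <- thickness_from_disparity(cal, dm)
    expect_lt(sqrt(mean((tm$thickness_mm[tm$valid] - t)^2)), 0.02)
  }
})

test_that("per-pixel calibration absorbs a tilted imaging plane", {
  cal <- rendered_calibration(tilt_deg = 1)
  rig <- test_rig()
  field <- test_field()
  pair <- render_stereo_pair(field, flat_depth_field(rig, 2.5, tilt_deg = 1),
                             rig, noise_model = NULL)
  dm <- match_disparity(pair, test_match_cfg(),
                        center = pred_disp(rig, 2.5), roi = test_roi)
  tm <- thickness_from_disparity(cal, dm)
  expect_lt(sqrt(mean((tm$thickness_mm[tm$valid] - 2.5)^2)), 0.02)
})

test_that("the field-of-view model reproduces its anchors and interpolates", {
  fv <- fov_scale(sop_default_fov_anchors(), 4)
  expect_equal(fv$width_mm, 10.7)
  expect_equal(fv$height_mm, 8.4)
  fv0 <- fov_scale(sop_default_fov_anchors(), 0)
  expect_equal(fv0$width_mm, 8.9)
  expect_equal(fv0$height_mm, 6.9)
  fv2 <- fov_scale(sop_default_fov_anchors(), 2)
  expect_equal(fv2$width_mm, 9.8)
  expect_equal(fv2$height_mm, 7.65)
  expect_false(fv2$extrapolated)
  expect_true(fov_scale(sop_default_fov_anchors(), 5)$extrapolated)
  # rig-derived anchors carry a consistent pixel scale
  rig <- test_rig()
  fa <- fov_anchors_from_rig(rig)
  expect_equal(fov_scale(fa, 0)$mm_per_px[["x"]],
               rig$z_contact_mm / rig$focal_px)
})

test_that("the .sopcal container round-trips bit-exactly", {
  cal <- rendered_calibration()
  p1 <- tempfile(fileext = ".sopcal")
  p2 <- tempfile(fileext = ".sopcal")
  write_sopcal(cal, p1)
  cal2 <- read_sopcal(p1)
  write_sopcal(cal2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  # values agree to float32 precision
  expect_equal(cal2$slope_px_per_mm, cal$slope_px_per_mm, tolerance = 1e-6)
  expect_identical(cal2$valid, cal$valid)
  expect_equal(cal2$fov$width_mm, cal$fov$width_mm, tolerance = 1e-12)
  # applying the reloaded model matches the original inversion closely
  rig <- test_rig()
  pair <- render_stereo_pair(test_field(), flat_depth_field(rig, 3), rig,
                             noise_model = NULL)
  dm <- match_disparity(pair, test_match_cfg(), center = pred_disp(rig, 3),
                        roi = test_roi)
  t1 <- thickness_from_disparity(cal, dm)
  t2 <- thickness_from_disparity(cal2, dm)
  expect_equal(t1$thickness_mm, t2$thickness_mm, tolerance = 1e-5)
})
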