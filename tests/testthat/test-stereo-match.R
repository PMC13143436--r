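test_that("quadratic sub-pixel refinement reproduces parabola vertices", {
  expect_equal(subpixel_refine(1, 0, 1)$offset, 0)
  # costs sampled from (delta - 0.3)^2 at -1, 0, 1
  expect_equal(subpixel_refine(1.69, 0.09, 0.49)$offset, 0.3)
  expect_equal(subpixel_refine(2, 1, 2)$offset,
               subpixel_refine(4, 2, 4)$offset)
  d <- subpixel_refine(1, 1, 1)
  expect_equal(d$offset, 0)
  expect_true(d$degenerate)
  expect_error(subpixel_refine(0.1, 0.5, 0.4), "invalid-argument")
  # random parabolas with a known vertex inside (-1, 1)
  set.seed(3)
  for (k in 1:20) {
    v <- runif(1, -0.45, 0.45)
    a <- runif(1, 0.1, 5)
    c0 <- runif(1, 0, 2)
    costs <- a * ((-1:1) - v)^2 + c0
    expect_equal(subpixel_refine(costs[1], costs[2], costs[3])$offset, v,
                 tolerance = 1e-12)
  }
})

test_that("an exact integer translation is recovered as exactly that shift", {
  rig <- test_rig()
  pair <- render_stereo_pair(test_field(), flat_depth_field(rig, 2), rig,
                             noise_model = NULL)
  sh <- 10L
  right <- cbind(pair$left[, -(1:sh)], matrix(0, nrow(pair$left), sh))
  dm <- match_disparity(list(left = pair$left, right = right),
                        test_match_cfg(), center = sh, roi = test_roi)
  expect_gt(mean(dm$valid), 0.9)
  expect_true(all(dm$disparity[dm$valid] == sh))
})

test_that("a synthetic half-pixel shift is recovered within 0.1 px", {
  rig <- test_rig()
  pair <- render_stereo_pair(test_field(), flat_depth_field(rig, 2), rig,
                             noise_model = NULL, bit_depth = 16)
  right <- t(apply(pair$left, 1, function(row)
    stats::spline(seq_along(row), row, xout = seq_along(row) + 0.5)$y))
  dm <- match_disparity(list(left = pair$left, right = right),
                        test_match_cfg(), center = 0, roi = test_roi)
  expect_lt(abs(mean(dm$disparity[dm$valid]) - 0.5), 0.1)
})

test_that("a rendered flat scene matches the stereoscopy prediction", {
  rig <- test_rig()
  for (thick in c(0, 2)) {
    pair <- render_stereo_pair(test_field(), flat_depth_field(rig, thick),
                               rig, noise_model = NULL)
    truth <- pred_disp(rig, thick)
    dm <- match_disparity(pair, test_match_cfg(), center = truth,
                          roi = test_roi)
    err <- dm$disparity[dm$valid] - truth
    expect_lt(abs(mean(err)), 0.1)
    expect_lt(sqrt(mean(err^2)), 0.15)
  }
})

test_that("the normalized cost is invariant to affine intensity changes", {
  rig <- test_rig()
  pair <- render_stereo_pair(test_field(), flat_depth_field(rig, 2), rig,
                             noise_model = NULL, bit_depth = 0L)
  truth <- pred_disp(rig, 2)
  base <- match_disparity(pair, test_match_cfg(), center = truth,
                          roi = test_roi)
  warped <- list(left = pair$left, right = 0.6 * pair$right + 0.15)
  dm <- match_disparity(warped, test_match_cfg(), center = truth,
                        roi = test_roi)
  expect_equal(dm$disparity, base$disparity, tolerance = 1e-9)
  expect_identical(dm$valid, base$valid)
})

test_that("degenerate windows are masked rather than raising errors", {
  flat <- list(left = matrix(0.5, 80, 120), right = matrix(0.5, 80, 120))
  dm <- match_disparity(flat, test_match_cfg(), center = 0,
                        roi = c(30L, 90L, 30L, 50L))
  expect_false(any(dm$valid))
  expect_error(match_config(search_halfwidth_px = 0), "invalid-argument")
  expect_error(match_config(window_diameter_px = 10), "invalid-argument")
})

test_that("the accelerated matcher agrees with exhaustive cost evaluation", {
  rig <- test_rig()
  pair <- render_stereo_pair(test_field(), flat_depth_field(rig, 2), rig,
                             noise_model = NULL)
  cfg <- test_match_cfg()
  truth <- round(pred_disp(rig, 2))
  dm <- match_disparity(pair, cfg, center = truth, roi = test_roi)
  off <- sopal:::.window_offsets(cfg$window_diameter_px)
  set.seed(1)
  # reference implementation of the cost at a handful of pixels
  ref_cost <- function(x, y, d) {
    a <- pair$left[cbind(y + off$dy, x + off$dx)]
    b <- pair$right[cbind(y + off$dy, x - d + off$dx)]
    a <- a - mean(a); b <- b - mean(b)
    2 * (1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  }
  for (k in 1:6) {
    x <- sample(seq(170L, test_roi[2]), 1)  # keep candidate windows in-bounds
    y <- sample(seq(test_roi[3], test_roi[4]), 1)
    cands <- (truth - 8):(truth + 8)
    curve <- match_cost_curve(pair, x, y, cands, cfg)
    rr <- vapply(cands, function(d) ref_cost(x, y, d), 0)
    expect_equal(curve, rr, tolerance = 1e-12)
    # integer stage: the refined disparity sits within one pixel of the
    # exhaustive argmin (refinement offset is bounded by (-1, 1))
    ix <- y - test_roi[3] + 1L
    jx <- x - test_roi[1] + 1L
    if (dm$valid[ix, jx])
      expect_lt(abs(dm$disparity[ix, jx] - cands[which.min(curve)]), 1)
  }
})

test_that("live decimated matching is consistent with the full map", {
  rig <- test_rig()
  pair <- render_stereo_pair(test_field(), flat_depth_field(rig, 2), rig,
                             noise_model = NULL)
  truth <- pred_disp(rig, 2)
  cfg <- match_config(search_halfwidth_px = 8, decimation = 2L)
  full <- match_disparity(pair, test_match_cfg(), center = truth,
                          roi = test_roi)
  live <- match_live(pair, cfg, center = truth, roi = test_roi)
  nx <- (test_roi[2] - test_roi[1]) %/% 2L + 1L
  ny <- (test_roi[4] - test_roi[3]) %/% 2L + 1L
  expect_equal(dim(live$disparity), c(ny, nx))
  expect_true(live$decimated)
  expect_equal(live$grid_pitch_px, 2L)
  both <- live$valid & full$valid[seq(1, nrow(full$valid), 2),
                                  seq(1, ncol(full$valid), 2)]
  dif <- live$disparity[both] -
    full$disparity[seq(1, nrow(full$valid), 2),
                   seq(1, ncol(full$valid), 2)][both]
  expect_lt(mean(abs(dif)), 0.2)
  up <- upsample_disparity(live)
  expect_equal(dim(up$disparity), dim(full$disparity))
  expect_equal(up$step, 1L)
  expect_gt(mean(up$valid), 0.9)
  expect_error(match_live(pair, match_config(), center = truth),
               "decimation")
})
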