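make_stress_map <- function(m, mm_per_px = c(0.05, 0.05), valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(m), ncol(m))
  structure(list(stress_kPa = m, valid = valid, measure = "true",
                 method = "algebraic", mm_per_px = mm_per_px,
                 roi = c(1L, ncol(m), 1L, nrow(m)), step = 1L),
            class = "sop_stress_map")
}

test_that("profiles are extracted with bilinear sampling in mm", {
  u <- make_stress_map(matrix(4, 41, 41))
  p <- extract_profile(u, c(21, 21), c(1, 0), 0.9)
  expect_true(all(p$stress_kPa == 4))
  # separable map: profile along x equals the corresponding row
  m <- outer(rep(1, 41), sin(seq(0, 3, length.out = 41)) + 2)
  s <- make_stress_map(m)
  p2 <- extract_profile(s, c(1, 21), c(1, 0), 2, step_mm = 0.05)
  expect_equal(p2$stress_kPa, m[21, 1:41], tolerance = 1e-9)
  expect_error(extract_profile(u, c(40, 21), c(1, 0), 2),
               "exits the map")
})

test_that("stress contrast is the center-over-background ratio", {
  u <- make_stress_map(matrix(3, 61, 61))
  expect_equal(stress_contrast(u, c(31, 31)), 1)
  # two-level map: 2 kPa inside the inclusion, 1 kPa outside
  m <- matrix(1, 61, 61)
  xy <- expand.grid(1:61, 1:61)
  r <- sqrt((xy[[1]] - 31)^2 + (xy[[2]] - 31)^2) * 0.05
  m[r <= 0.45] <- 2
  two <- make_stress_map(m)
  expect_equal(stress_contrast(two, c(31, 31)), 2)
  # invariant to global rescaling
  expect_equal(stress_contrast(make_stress_map(7 * m), c(31, 31)), 2)
  expect_error(stress_contrast(make_stress_map(0 * m), c(31, 31)),
               "undefined-contrast")
  expect_error(stress_contrast(two, c(31, 31), background_radii_mm = c(0.3, 1)),
               "overlaps")
  # profile method agrees on a revolved two-level profile
  prof <- data.frame(position_mm = seq(0, 1.5, by = 0.01),
                     stress_kPa = ifelse(seq(0, 1.5, by = 0.01) <= 0.45, 2, 1))
  expect_equal(stress_contrast(prof), 2)
})

test_that("resolution equals the analytic FWHM of an error-function edge", {
  x <- seq(0, 3, by = 0.005)
  for (sigma in c(0.1, 0.2)) {
    prof <- data.frame(position_mm = x,
                       stress_kPa = 2 - pnorm((x - 1.5) / sigma))
    r <- stress_resolution(prof)
    expect_true(r$defined)
    expect_lt(abs(r$fwhm_um / (2 * sqrt(2 * log(2)) * sigma * 1000) - 1),
              0.02)
    # invariant to rescaling and mirroring
    prof2 <- prof
    prof2$stress_kPa <- 5 * rev(prof$stress_kPa)
    expect_equal(stress_resolution(prof2)$fwhm_um, r$fwhm_um,
                 tolerance = 1e-9)
  }
})

test_that("an ideal step resolves to at most two sample pitches", {
  for (p in c(0.02, 0.05)) {
    x <- seq(0, 2, by = p)
    prof <- data.frame(position_mm = x, stress_kPa = as.numeric(x >= 1))
    r <- stress_resolution(prof)
    expect_true(r$defined)
    expect_lte(r$fwhm_um, 2 * p * 1000 + 1e-9)
  }
})

test_that("smoothing a profile strictly widens its resolution", {
  x <- seq(0, 3, by = 0.01)
  y <- 2 - pnorm((x - 1.5) / 0.15)
  f0 <- stress_resolution(data.frame(position_mm = x, stress_kPa = y))$fwhm_um
  ys <- stats::filter(y, rep(1 / 21, 21), sides = 2)
  ok <- !is.na(ys)
  f1 <- stress_resolution(data.frame(position_mm = x[ok],
                                     stress_kPa = as.numeric(ys[ok])))$fwhm_um
  expect_gt(f1, f0)
})

test_that("profiles without half-maximum crossings are flagged undefined", {
  x <- seq(0, 2, by = 0.01)
  r <- stress_resolution(data.frame(position_mm = x, stress_kPa = 3 * x))
  expect_false(r$defined)
  expect_true(is.na(r$fwhm_um))
})

test_that("the metrics report bundles deterministic contrast and resolution", {
  m <- matrix(1, 81, 81)
  xy <- expand.grid(1:81, 1:81)
  r <- sqrt((xy[[1]] - 41)^2 + (xy[[2]] - 41)^2) * 0.05
  m[] <- 1 + pnorm((0.4 - r) / 0.1)
  map <- make_stress_map(m)
  rep1 <- metrics_report(map, c(41, 41), profile_length_mm = 1.8)
  rep2 <- metrics_report(map, c(41, 41), profile_length_mm = 1.8)
  expect_identical(rep1$contrast, rep2$contrast)
  expect_identical(rep1$resolution_um, rep2$resolution_um)
  expect_gt(rep1$contrast, 1.5)
  expect_true(is.finite(rep1$resolution_um))
})
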