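test_that("strain from thickness follows the bulk-strain definition", {
  m <- fake_thickness_map(matrix(c(5, 3, 2.5, 6), 2, 2))
  s <- strain_from_thickness(m, 5)
  expect_equal(s$strain[1, 1], 0)
  expect_equal(s$strain[2, 1], 0.4)
  expect_equal(s$strain[1, 2], 0.5)
  # d > L0 gives a flagged negative strain, invalidated
  expect_true(s$negative[2, 2])
  expect_false(s$valid[2, 2])
  expect_error(strain_from_thickness(m, -1), "invalid-argument")
  # chain is exactly invertible: thickness -> strain -> thickness
  d <- matrix(runif(30, 2, 5), 5, 6)
  eps <- strain_from_thickness(fake_thickness_map(d), 5)
  expect_equal((1 - eps$strain) * 5, d, tolerance = 1e-15)
})

test_that("the Neo-Hookean fit recovers a known C10 and rejects bad tables", {
  tb <- synthetic_stress_strain_table(2.83)
  fit <- fit_neo_hookean(tb)
  expect_lt(abs(fit$C10_kPa / 2.83 - 1), 0.01)
  expect_equal(neo_hookean_stress(0, fit$C10_kPa), 0)
  # small-strain slope equals E = 6 C10
  h <- 1e-7
  slope <- (neo_hookean_stress(h, 2.83) - neo_hookean_stress(0, 2.83)) / h
  expect_equal(slope, 6 * 2.83, tolerance = 1e-5)
  # noisy table still recovers within 1%
  tbn <- synthetic_stress_strain_table(2.83, noise_sd_kPa = 0.05, seed = 4)
  expect_lt(abs(fit_neo_hookean(tbn)$C10_kPa / 2.83 - 1), 0.01)
  expect_error(fit_neo_hookean(tb[1:2, ]), "invalid-data")
  expect_error(fit_neo_hookean(data.frame(strain = c(0, 0.1, 0.15),
                                          stress_kPa = c(0, 1, 2))),
               "invalid-data")
  bad <- tb
  bad$stress_kPa[10] <- -1
  expect_error(fit_neo_hookean(bad), "invalid-data")
  nonmono <- tb
  nonmono$stress_kPa[8] <- nonmono$stress_kPa[12]
  expect_error(fit_neo_hookean(nonmono), "invalid-data")
})

test_that("the uniaxial law is evaluated correctly and monotonically", {
  # 2 * 2.83 * (1/0.6^2 - 0.6) = 12.33 kPa at 40% compression
  expect_equal(neo_hookean_stress(0.4, 2.83),
               2 * 2.83 * (1 / 0.36 - 0.6), tolerance = 1e-12)
  expect_equal(round(neo_hookean_stress(0.4, 2.83), 1), 12.3)
  eps <- seq(0, 0.55, by = 0.01)
  expect_true(all(diff(neo_hookean_stress(eps, 2.83)) > 0))
  model <- layer_model()
  s <- strain_from_thickness(fake_thickness_map(matrix(c(3, 2.8), 1, 2)), 5)
  sm <- stress_from_strain(model, s)
  expect_lt(sm$stress_kPa[1, 1], sm$stress_kPa[1, 2])
  expect_equal(sm$measure, "engineering")
})

test_that("fitted law agrees with the source stress-strain table", {
  tb <- synthetic_stress_strain_table(2.83, noise_sd_kPa = 0.03, seed = 7)
  fit <- fit_neo_hookean(tb)
  pred <- neo_hookean_stress(tb$strain, fit$C10_kPa)
  expect_lt(sqrt(mean((pred - tb$stress_kPa)^2)), fit$fit_rms_kPa + 1e-9)
  # dense numerical inversion of the table matches the law within fit RMS
  dense <- stats::approx(tb$strain, tb$stress_kPa,
                         xout = seq(0.05, 0.45, by = 0.01))$y
  lawv <- neo_hookean_stress(seq(0.05, 0.45, by = 0.01), fit$C10_kPa)
  expect_lt(max(abs(dense - lawv)), 3 * fit$fit_rms_kPa + 0.05)
})

test_that("true stress applies the (1 + strain) presentation factor", {
  eps <- structure(list(strain = matrix(c(0, 0.4, 0.5), 1, 3),
                        valid = matrix(TRUE, 1, 3),
                        negative = matrix(FALSE, 1, 3),
                        roi = NULL, step = 1L, L0_mm = 5),
                   class = "sop_strain_map")
  se <- structure(list(stress_kPa = matrix(c(7, 10, 8), 1, 3),
                       valid = matrix(TRUE, 1, 3), measure = "engineering",
                       method = "algebraic", mm_per_px = c(NA, NA),
                       roi = NULL, step = 1L),
                  class = "sop_stress_map")
  st <- true_stress(se, eps)
  expect_equal(st$stress_kPa[1, ], c(7, 14, 12))
  expect_equal(st$measure, "true")
  eps2 <- eps
  eps2$strain <- matrix(0, 2, 2)
  expect_error(true_stress(se, eps2), "not aligned")
})

test_that("the algebraic chain is monotone and propagates masks", {
  model <- layer_model()
  d <- matrix(3, 6, 6)
  u <- algebraic_stress_map(fake_thickness_map(d), model)
  expect_equal(max(u$stress_kPa) - min(u$stress_kPa), 0)
  d2 <- d
  d2[3, 3] <- 2.5  # thinner region
  v <- algebraic_stress_map(fake_thickness_map(d2), model)
  expect_gt(v$stress_kPa[3, 3], v$stress_kPa[1, 1])
  d3 <- d
  d3[2, 5] <- NA
  w <- algebraic_stress_map(fake_thickness_map(d3), model)
  expect_false(w$valid[2, 5])
  expect_true(is.na(w$stress_kPa[2, 5]))
  # homogeneous pipeline returns the uniaxial presentation value within 1%
  lam <- 3 / 5
  expected <- 2 * model$C10_kPa * (1 / lam^2 - lam) * (1 + (1 - lam))
  expect_lt(abs(u$stress_kPa[1, 1] / expected - 1), 0.01)
})

test_that("layer model validation enforces physical parameters", {
  expect_error(layer_model(C10_kPa = -1), "invalid-argument")
  expect_error(layer_model(poisson_ratio = 0.5), "invalid-argument")
  expect_error(layer_model(L0_mm = 0), "invalid-argument")
  m <- layer_model()
  expect_equal(fe_bulk_modulus(m),
               2 * 2.83 * 1.49 / (3 * 0.02), tolerance = 1e-12)
})
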