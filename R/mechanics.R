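#' Compliant layer material model
#'
#' Neo-Hookean description of the silicone sensing layer. The incompressible
#' uniaxial law used by the algebraic stress chain is
#' `sigma_E = 2 C10 (1/lambda^2 - lambda)` with stretch `lambda = 1 - eps_E`
#' under the compressive-positive sign convention (both strain and stress are
#' reported as positive magnitudes in compression). The small-strain Young's
#' modulus is `E = 6 C10`; the default `C10 = 2.83` kPa corresponds to the
#' layer silicone's ~17 kPa modulus. `poisson_ratio` parameterizes the
#' near-incompressible volumetric penalty used by the finite-element solver
#' (see [fe_bulk_modulus()]).
#'
#' @param L0_mm Uncompressed layer thickness (mm), default 5.
#' @param C10_kPa Neo-Hookean shear coefficient (kPa), > 0.
#' @param poisson_ratio In (0, 0.5); default 0.49.
#' @param table Optional source stress-strain data frame
#'   (`strain`, `stress_kPa`, engineering, compressive-positive).
#' @param fit_rms_kPa RMS of the fit to `table`, when fitted.
#' @return Object of class `sop_layer_model`.
#' @export
layer_model <- function(L0_mm = 5, C10_kPa = 2.83, poisson_ratio = 0.49,
                        table = NULL, fit_rms_kPa = NULL) {
  if (L0_mm <= 0) stop("invalid-argument: L0_mm must be > 0")
  if (C10_kPa <= 0) stop("invalid-argument: C10_kPa must be > 0")
  if (poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("invalid-argument: poisson_ratio must be in (0, 0.5)")
  structure(list(L0_mm = L0_mm, C10_kPa = C10_kPa,
                 poisson_ratio = poisson_ratio, table = table,
                 fit_rms_kPa = fit_rms_kPa),
            class = "sop_layer_model")
}

#' @export
print.sop_layer_model <- function(x, ...) {
  cat(sprintf(
    "<sop_layer_model> L0 = %.2f mm, C10 = %.3f kPa (E ~ %.1f kPa), nu = %.3f\n",
    x$L0_mm, x$C10_kPa, 6 * x$C10_kPa, x$poisson_ratio))
  if (!is.null(x$fit_rms_kPa))
    cat(sprintf("  fitted from %d-point table, RMS %.4f kPa\n",
                nrow(x$table), x$fit_rms_kPa))
  invisible(x)
}

#' Bulk modulus of the near-incompressible finite-element material
#'
#' `K = 2 C10 (1 + nu) / (3 (1 - 2 nu))`, i.e. the linear-elastic bulk
#' modulus consistent with shear modulus `mu = 2 C10` and the model's
#' Poisson ratio.
#'
#' @param model An [layer_model()].
#' @return Bulk modulus (kPa).
#' @export
fe_bulk_modulus <- function(model) {
  2 * model$C10_kPa * (1 + model$poisson_ratio) /
    (3 * (1 - 2 * model$poisson_ratio))
}

#' Incompressible uniaxial Neo-Hookean engineering stress
#'
#' @param strain Engineering strain (compressive-positive, < 1).
#' @param C10_kPa Shear coefficient (kPa).
#' @return Engineering stress magnitude (kPa, compressive-positive).
#' @export
neo_hookean_stress <- function(strain, C10_kPa) {
  lam <- 1 - strain
  2 * C10_kPa * (1 / lam^2 - lam)
}

#' Synthetic uniaxial compression table
#'
#' Generates the engineering stress-strain table of an incompressible
#' Neo-Hookean material, standing in for the layer's uniaxial compression
#' characterization (the probe's layer is characterized by averaging three
#' compression tests; no tabulated data ships with the probe, so this
#' synthetic table is the default fixture).
#'
#' @param C10_kPa Shear coefficient (kPa).
#' @param strains Engineering strain samples (compressive-positive).
#' @param noise_sd_kPa Optional Gaussian noise on the stress column.
#' @param seed Seed used when `noise_sd_kPa > 0`.
#' @return Data frame with `strain` and `stress_kPa`.
#' @export
synthetic_stress_strain_table <- function(C10_kPa = 2.83,
                                          strains = seq(0, 0.5, by = 0.025),
                                          noise_sd_kPa = 0, seed = 1L) {
  s <- neo_hookean_stress(strains, C10_kPa)
  if (noise_sd_kPa > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    s <- s + stats::rnorm(length(s), 0, noise_sd_kPa)
  }
  data.frame(strain = strains, stress_kPa = s)
}

#' Fit a Neo-Hookean model to uniaxial compression data
#'
#' Least-squares fit of `sigma_E = 2 C10 (1/lambda^2 - lambda)`,
#' `lambda = 1 - eps_E`, to an engineering stress-strain table
#' (compressive-positive). The law is linear in `C10`, so the fit is closed
#' form; residuals are minimized on engineering stress.
#'
#' @param table Data frame with columns `strain` and `stress_kPa`; at least
#'   3 samples spanning strain > 0.2, non-negative and non-decreasing stress.
#' @param L0_mm,poisson_ratio Passed through to [layer_model()].
#' @return An [layer_model()] with `table` and `fit_rms_kPa` attached.
#' @export
fit_neo_hookean <- function(table, L0_mm = 5, poisson_ratio = 0.49) {
  if (!all(c("strain", "stress_kPa") %in% names(table)))
    stop("invalid-data: table needs columns strain, stress_kPa")
  tb <- table[order(table$strain), ]
  if (nrow(tb) < 3L) stop("invalid-data: need >= 3 samples")
  if (diff(range(tb$strain)) <= 0.2)
    stop("invalid-data: strain range must span > 0.2")
  if (any(tb$stress_kPa < -1e-9))
    stop("invalid-data: negative stress in table")
  if (any(diff(tb$stress_kPa) < -1e-9 - 1e-6 * max(abs(tb$stress_kPa))))
    stop("invalid-data: non-monotone stress table")
  g <- neo_hookean_stress(tb$strain, 1)  # basis: the law at unit C10
  C10 <- sum(g * tb$stress_kPa) / sum(g^2)
  if (C10 <= 0) stop("invalid-data: fit produced non-positive C10")
  rms <- sqrt(mean((tb$stress_kPa - neo_hookean_stress(tb$strain, C10))^2))
  layer_model(L0_mm = L0_mm, C10_kPa = C10, poisson_ratio = poisson_ratio,
              table = tb, fit_rms_kPa = rms)
}

#' Engineering strain map from a thickness map
#'
#' `eps_E = (L0 - d) / L0` per pixel (compressive-positive). Pixels with
#' `d > L0` (negative strain) are flagged and invalidated; masks propagate.
#'
#' @param thickness An [thickness_from_disparity()] map, or a plain numeric
#'   matrix of thicknesses (mm).
#' @param L0_mm Uncompressed layer thickness (mm), > 0.
#' @return Object of class `sop_strain_map` (`strain`, `valid`, `negative`).
#' @export
strain_from_thickness <- function(thickness, L0_mm) {
  if (L0_mm <= 0) stop("invalid-argument: L0_mm must be > 0")
  if (is.matrix(thickness))
    thickness <- structure(list(thickness_mm = thickness,
                                valid = is.finite(thickness),
                                roi = NULL, step = 1L),
                           class = "sop_thickness_map")
  stopifnot(inherits(thickness, "sop_thickness_map"))
  eps <- (L0_mm - thickness$thickness_mm) / L0_mm
  neg <- thickness$valid & is.finite(eps) & eps < 0
  valid <- thickness$valid & is.finite(eps) & !neg
  eps[!thickness$valid] <- NA
  structure(list(strain = eps, valid = valid, negative = neg,
                 roi = thickness$roi, step = thickness$step,
                 L0_mm = L0_mm),
            class = "sop_strain_map")
}

.stress_map <- function(stress, valid, measure, method, mm_per_px, roi, step) {
  structure(list(stress_kPa = stress, valid = valid, measure = measure,
                 method = method, mm_per_px = mm_per_px, roi = roi,
                 step = step),
            class = "sop_stress_map")
}

#' @export
print.sop_stress_map <- function(x, ...) {
  cat(sprintf("<sop_stress_map> %s %s stress, %d x %d, %.1f%% valid\n",
              x$method, x$measure, ncol(x$stress_kPa), nrow(x$stress_kPa),
              100 * mean(x$valid)))
  invisible(x)
}

#' Engineering stress map from a strain map
#'
#' Per-pixel evaluation of the layer's fitted uniaxial law (strictly
#' increasing in strain).
#'
#' @param model An [layer_model()].
#' @param strain An [strain_from_thickness()] map.
#' @param mm_per_px Pixel pitch `c(x, y)` in mm, if known.
#' @return An engineering-measure `sop_stress_map`.
#' @export
stress_from_strain <- function(model, strain, mm_per_px = c(NA, NA)) {
  stopifnot(inherits(model, "sop_layer_model"),
            inherits(strain, "sop_strain_map"))
  s <- neo_hookean_stress(strain$strain, model$C10_kPa)
  s[!strain$valid] <- NA
  .stress_map(s, strain$valid, "engineering", "algebraic", mm_per_px,
              strain$roi, strain$step)
}

#' Convert engineering stress to true stress
#'
#' `sigma_T = sigma_E (1 + eps_E)` per pixel: under the compressive-positive
#' convention the deformed cross-section carrying the load is smaller than
#' the reference one by the factor `1/(1 + eps_E)`.
#'
#' @param engineering An engineering-measure `sop_stress_map`.
#' @param strain The aligned `sop_strain_map`.
#' @return A true-measure `sop_stress_map`.
#' @export
true_stress <- function(engineering, strain) {
  stopifnot(inherits(engineering, "sop_stress_map"),
            inherits(strain, "sop_strain_map"))
  if (engineering$measure != "engineering")
    stop("invalid-argument: input must be an engineering stress map")
  if (!all(dim(engineering$stress_kPa) == dim(strain$strain)))
    stop("invalid-argument: maps are not aligned")
  valid <- engineering$valid & strain$valid
  s <- engineering$stress_kPa * (1 + strain$strain)
  s[!valid] <- NA
  .stress_map(s, valid, "true", engineering$method, engineering$mm_per_px,
              engineering$roi, engineering$step)
}

#' Algebraic true-stress map from a thickness map
#'
#' The full algebraic chain: bulk engineering strain from thickness, the
#' layer's uniaxial Neo-Hookean law, and conversion to true stress. Assumes
#' frictionless, depth-uniform uniaxial stress in the layer.
#'
#' @param thickness An `sop_thickness_map` (or numeric matrix, mm).
#' @param model An [layer_model()].
#' @param mm_per_px Pixel pitch `c(x, y)` in mm, if known.
#' @return A true-measure, algebraic-method `sop_stress_map`.
#' @export
algebraic_stress_map <- function(thickness, model, mm_per_px = c(NA, NA)) {
  eps <- strain_from_thickness(thickness, model$L0_mm)
  sigE <- stress_from_strain(model, eps, mm_per_px = mm_per_px)
  true_stress(sigE, eps)
}
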