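# Shared fixtures: a small fast rig, sparse particle fields, fabricated map
# objects, and the independent closed-form uniaxial oracle.

test_rig <- function(image = c(420L, 260L)) {
  camera_rig(focal_px = 2760, image_size_px = image, z_contact_mm = 120)
}

test_field <- function(seed = 11, density = 10, rig = test_rig()) {
  make_particle_field(seed, density_per_mm2 = density,
                      center_mm = c(rig$baseline_mm / 2, 0))
}

test_roi <- c(120L, 330L, 60L, 190L)

test_match_cfg <- function(...) match_config(search_halfwidth_px = 8, ...)

pred_disp <- function(rig, thickness_mm) {
  rig$baseline_mm * rig$focal_px / (rig$z_contact_mm + thickness_mm)
}

# fabricate a disparity-map object from a plain matrix
fake_disparity_map <- function(m, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(m), ncol(m))
  structure(list(disparity = m, valid = valid,
                 cost = matrix(0, nrow(m), ncol(m)),
                 degenerate = matrix(FALSE, nrow(m), ncol(m)),
                 roi = c(1L, ncol(m), 1L, nrow(m)), step = 1L,
                 window_diameter_px = 35L, search_range = c(-8L, 8L),
                 decimated = FALSE, grid_pitch_px = 1L),
            class = "sop_disparity_map")
}

fake_thickness_map <- function(m, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(m)
  structure(list(thickness_mm = m, valid = valid,
                 flagged = matrix(FALSE, nrow(m), ncol(m)),
                 roi = c(1L, ncol(m), 1L, nrow(m)), step = 1L,
                 mean_thickness_mm = mean(m[valid])),
            class = "sop_thickness_map")
}

# Independent closed-form homogeneous uniaxial solution for the compressible
# Neo-Hookean solid: minimize the energy density over the lateral stretch at
# fixed axial stretch; axial stresses by numerical differentiation.
uniaxial_oracle <- function(lam_z, C10, K) {
  W <- function(lr, lz) {
    J <- lr^2 * lz
    C10 * (J^(-2 / 3) * (2 * lr^2 + lz^2) - 3) + K / 2 * (J - 1)^2
  }
  lr <- stats::optimize(function(l) W(l, lam_z), c(0.4, 2.5),
                        tol = 1e-12)$minimum
  h <- 1e-6
  Pzz <- (W(lr, lam_z + h) - W(lr, lam_z - h)) / (2 * h)
  J <- lr^2 * lam_z
  list(lateral_stretch = lr, eng_stress = Pzz, cauchy = Pzz * lam_z / J,
       J = J)
}

# render a flat calibration stack and match it on the test ROI
rendered_calibration <- function(rig = test_rig(), field = test_field(),
                                 thicknesses = 0:4, tilt_deg = 0,
                                 roi = test_roi, cfg = test_match_cfg()) {
  stack <- make_calibration_stack(rig, field, thicknesses, tilt_deg = tilt_deg,
                                  noise_model = NULL)
  maps <- lapply(stack, function(s) {
    list(thickness_mm = s$thickness_mm,
         map = match_disparity(s$pair, cfg,
                               center = pred_disp(rig, s$thickness_mm),
                               roi = roi))
  })
  fit_disparity_thickness(maps, fov_anchors_from_rig(rig))
}
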