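#' Pipeline configuration
#'
#' Bundles every stage's parameters for the end-to-end processing chain and
#' the in-silico benchmark. All randomness derives from `seed`.
#'
#' @param rig A [camera_rig()].
#' @param layer An [layer_model()].
#' @param match A [match_config()].
#' @param compop An [compop_config()].
#' @param seed Integer seed.
#' @param calibration_thicknesses_mm Flat-plane calibration protocol (mm).
#' @param particle_density_per_mm2 Particle density of the synthetic layer.
#' @param roi_half_mm `c(x, y)` half-extent of the processed region (mm).
#' @param profile_length_mm Metrics profile length (mm).
#' @param inclusion_radius_mm Inclusion radius used by the metrics regions.
#' @param noise_model A [render_noise()] or `NULL` (noiseless benchmark).
#' @param verbose Log stage messages to stderr.
#' @return Object of class `sop_pipeline_config`.
#' @export
pipeline_config <- function(rig = camera_rig(), layer = layer_model(),
                            match = match_config(search_halfwidth_px = 15L),
                            compop = compop_config(element_size_mm = 0.15),
                            seed = 1L,
                            calibration_thicknesses_mm = 0:4,
                            particle_density_per_mm2 = 150,
                            roi_half_mm = c(4, 1.3),
                            profile_length_mm = 3,
                            inclusion_radius_mm = 0.4,
                            noise_model = NULL,
                            verbose = FALSE) {
  structure(list(rig = rig, layer = layer, match = match, compop = compop,
                 seed = as.integer(seed),
                 calibration_thicknesses_mm = calibration_thicknesses_mm,
                 particle_density_per_mm2 = particle_density_per_mm2,
                 roi_half_mm = roi_half_mm,
                 profile_length_mm = profile_length_mm,
                 inclusion_radius_mm = inclusion_radius_mm,
                 noise_model = noise_model, verbose = verbose),
            class = "sop_pipeline_config")
}

.log_stage <- function(cfg, ...) {
  if (isTRUE(cfg$verbose))
    message(format(Sys.time(), "[%H:%M:%S] "), sprintf(...))
}

#' Provenance record for pipeline outputs
#'
#' @param config Any serializable configuration object.
#' @param seed The seed in force.
#' @return List with package version, seed and an md5 hash of the config.
#' @export
provenance <- function(config, seed = NA_integer_) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf)
  list(package = "sopal",
       version = as.character(utils::packageVersion("sopal")),
       seed = seed,
       config_md5 = unname(tools::md5sum(tf)))
}

# processed region centered on the scene axis, identical across the stack
# and the benchmark frame
.scene_roi <- function(cfg, scene_center_mm, mean_thickness_mm) {
  rig <- cfg$rig
  z <- rig$z_contact_mm + mean_thickness_mm
  ppx <- rig$focal_px / z
  c_px <- project_points(rig, scene_center_mm[1], scene_center_mm[2], z, "left")
  hw <- ceiling(cfg$roi_half_mm * ppx)
  roi <- c(round(c_px$x) - hw[1], round(c_px$x) + hw[1],
           round(c_px$y) - hw[2], round(c_px$y) + hw[2])
  list(roi = as.integer(roi), center_px = c(round(c_px$x), round(c_px$y)),
       center_local = c(round(c_px$x) - roi[1] + 1,
                        round(c_px$y) - roi[3] + 1))
}

#' Run the processing chain on a stereo dataset
#'
#' Executes disparity matching, calibration inversion, the algebraic stress
#' chain, computational optical palpation and the image-quality metrics on a
#' measured (or rendered) stereo pair. Any stage failure aborts with the
#' stage name and cause.
#'
#' @param pair An `sop_stereo_pair` of the compressed scene.
#' @param cal An `sop_calibration` for the same processed region.
#' @param config An [pipeline_config()].
#' @param center_px Inclusion/scene center `c(x, y)` in full-image pixels.
#' @param thickness_guess_mm Expected mean thickness used to center the
#'   disparity search.
#' @return List of class `sop_pipeline_result`: `disparity`, `thickness`,
#'   `algebraic`, `computational` stress maps, `metrics` (both methods),
#'   `fov`, `provenance`.
#' @export
run_pipeline <- function(pair, cal, config = pipeline_config(), center_px,
                         thickness_guess_mm = 3) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cfg <- config
  roi <- cal$roi
  .log_stage(cfg, "match: window %d px", cfg$match$window_diameter_px)
  disp <- stage("match", match_disparity(
    pair, cfg$match, center = predict_disparity(cal, thickness_guess_mm),
    roi = roi))
  .log_stage(cfg, "calibrate: inverting per-pixel fits")
  thk <- stage("calibrate", thickness_from_disparity(
    cal, disp, max_thickness_mm = cfg$layer$L0_mm))
  fov <- fov_scale(cal, thk$mean_thickness_mm)
  mpp <- fov$mm_per_px
  .log_stage(cfg, "mechanics: algebraic stress map")
  alg <- stage("stress-alg", algebraic_stress_map(thk, cfg$layer,
                                                  mm_per_px = mpp))
  center_local <- c(center_px[1] - roi[1] + 1, center_px[2] - roi[3] + 1)
  .log_stage(cfg, "compop: %s FE inversion", cfg$compop$geometry_mode)
  comp <- stage("stress-comp", computational_stress_map(
    thk, cfg$layer, cal, cfg$compop, center_px = center_local))
  .log_stage(cfg, "metrics")
  met <- stage("metrics", list(
    algebraic = metrics_report(alg, center_local,
                               inclusion_radius_mm = cfg$inclusion_radius_mm,
                               profile_length_mm = cfg$profile_length_mm),
    computational = metrics_report(comp, center_local,
                                   inclusion_radius_mm = cfg$inclusion_radius_mm,
                                   profile_length_mm = cfg$profile_length_mm)))
  structure(list(disparity = disp, thickness = thk, algebraic = alg,
                 computational = comp, metrics = met, fov = fov,
                 center_local = center_local,
                 provenance = provenance(cfg, cfg$seed)),
            class = "sop_pipeline_result")
}

#' In-silico phantom benchmark
#'
#' Reproduces the structured-phantom experiment fully in simulation:
#' an axisymmetric forward FE model of the layer-on-phantom compression
#' provides ground truth; stereo particle frames of the deformed layer and a
#' flat-plane calibration stack are rendered; the full measurement chain
#' (matching, per-pixel calibration, algebraic and computational stress
#' maps) is run; and the stress contrast and resolution of both methods are
#' reported alongside the forward-model ground truth.
#'
#' @param phantom A [phantom_spec()].
#' @param config An [pipeline_config()].
#' @param target_mean_strain Mean layer strain of the compression.
#' @param forward Optional precomputed [phantom_forward_model()] result for
#'   this phantom/layer/strain (recomputed when `NULL`).
#' @return List of class `sop_benchmark_report`: `metrics` (per method),
#'   `ground_truth`, `contrast_improvement_percent`, `forward`, `pipeline`,
#'   `calibration`, `provenance`.
#' @export
run_benchmark <- function(phantom = phantom_spec(),
                          config = pipeline_config(),
                          target_mean_strain = 0.4,
                          forward = NULL) {
  cfg <- config
  rig <- cfg$rig
  layer <- cfg$layer
  .log_stage(cfg, "forward: axisymmetric layer-on-phantom FE model")
  fwd <- if (is.null(forward)) phantom_forward_model(
    phantom, layer, target_mean_strain, cfg$compop) else forward
  scene_center <- c(rig$baseline_mm / 2, 0)
  mean_d <- layer$L0_mm * (1 - fwd$mean_strain)
  sr <- .scene_roi(cfg, scene_center, mean_d)

  .log_stage(cfg, "render: particle field seed %d", cfg$seed)
  field <- make_particle_field(cfg$seed, cfg$particle_density_per_mm2,
                               center_mm = scene_center)
  .log_stage(cfg, "render: calibration stack")
  stack <- make_calibration_stack(rig, field, cfg$calibration_thicknesses_mm,
                                  noise_model = cfg$noise_model)
  .log_stage(cfg, "match: calibration stack")
  maps <- lapply(stack, function(s) {
    pred <- rig$baseline_mm * rig$focal_px / (rig$z_contact_mm + s$thickness_mm)
    list(thickness_mm = s$thickness_mm,
         map = match_disparity(s$pair, cfg$match, center = pred,
                               roi = sr$roi))
  })
  cal <- fit_disparity_thickness(maps, fov_anchors_from_rig(rig))

  .log_stage(cfg, "render: deformed benchmark frame")
  field_def <- deform_particle_field(field, fwd$thickness$R0_mm,
                                     fwd$thickness$ur_mm)
  ext <- field$layer_diameter_mm / 2 + 1
  gx <- seq(scene_center[1] - ext, scene_center[1] + ext, by = 0.1)
  gy <- seq(scene_center[2] - ext, scene_center[2] + ext, by = 0.1)
  rr <- sqrt(outer(gy - scene_center[2], gx - scene_center[1],
                   function(a, b) a^2 + b^2))
  zz <- rig$z_contact_mm +
    matrix(stats::approx(fwd$thickness$r_mm, fwd$thickness$d_mm,
                         xout = rr, rule = 2)$y, length(gy), length(gx))
  dfield <- depth_field(gx, gy, zz)
  pair <- render_stereo_pair(field_def, dfield, rig,
                             noise_model = cfg$noise_model)

  pipe <- run_pipeline(pair, cal, cfg, center_px = sr$center_px,
                       thickness_guess_mm = mean_d)

  # ground truth from the forward interface profiles
  gt_prof <- fwd$interface_stress
  gt_sym <- data.frame(position_mm = gt_prof$r_mm,
                       stress_kPa = gt_prof$stress_kPa)
  s <- seq(0, cfg$profile_length_mm, by = min(pipe$fov$mm_per_px))
  gt_uniform <- data.frame(
    position_mm = s,
    stress_kPa = stats::approx(gt_sym$position_mm, gt_sym$stress_kPa,
                               xout = s, rule = 2)$y)
  gt_res <- stress_resolution(gt_uniform)
  gt <- list(
    contrast = stress_contrast(gt_sym,
                               inclusion_radius_mm = cfg$inclusion_radius_mm),
    resolution_um = gt_res$fwhm_um,
    mean_strain = fwd$mean_strain,
    min_thickness_mm = min(fwd$thickness$d_mm))

  met <- pipe$metrics
  imp <- (met$computational$contrast / met$algebraic$contrast - 1) * 100
  structure(list(metrics = met, ground_truth = gt,
                 contrast_improvement_percent = imp,
                 forward = fwd, pipeline = pipe, calibration = cal,
                 phantom = phantom,
                 provenance = provenance(cfg, cfg$seed)),
            class = "sop_benchmark_report")
}

#' @export
print.sop_benchmark_report <- function(x, ...) {
  m <- x$metrics
  cat("<sop_benchmark_report>\n")
  cat(sprintf("  algebraic:     contrast %.3f, resolution %s\n",
              m$algebraic$contrast,
              if (is.finite(m$algebraic$resolution_um))
                sprintf("%.0f um", m$algebraic$resolution_um) else "undefined"))
  cat(sprintf("  computational: contrast %.3f, resolution %s\n",
              m$computational$contrast,
              if (is.finite(m$computational$resolution_um))
                sprintf("%.0f um", m$computational$resolution_um) else "undefined"))
  cat(sprintf("  contrast improvement %.1f%%\n",
              x$contrast_improvement_percent))
  cat(sprintf("  ground truth:  contrast %.3f, resolution %.0f um\n",
              x$ground_truth$contrast, x$ground_truth$resolution_um))
  invisible(x)
}

#' Inverse-consistency check of the computational method
#'
#' Feeds the forward phantom model's exact interface displacement (both
#' components, on an independently built layer mesh) back through the
#' computational solver and compares the recovered interface stress with the
#' forward model's, pointwise over the region away from the lateral contact
#' edge.
#'
#' @param forward A [phantom_forward_model()] result.
#' @param layer The [layer_model()] used in the forward model.
#' @param cfg An [compop_config()].
#' @param edge_margin_mm Region excluded near the lateral edge (mm).
#' @return List: `max_rel_error` over the compared region, the compared
#'   profiles, and the inverse `sop_fe_result`.
#' @export
inverse_consistency_check <- function(forward, layer, cfg = compop_config(),
                                      edge_margin_mm = 2) {
  thick <- forward$thickness
  extent <- max(thick$R0_mm)
  # radial nodes aligned with the forward interface nodes so the prescribed
  # displacement is exact at every node
  mesh <- build_layer_mesh(layer, extent, cfg, r_breaks = thick$R0_mm)
  res <- solve_layer_compression(
    mesh, layer,
    sample_profile = list(r_mm = thick$R0_mm,
                          uz_mm = layer$L0_mm - thick$d_mm,
                          ur_mm = thick$ur_mm, tangential = "prescribed"),
    cfg = cfg)
  inv <- interface_stress(res, mesh, "sample")
  fwd_on_inv <- stats::approx(forward$interface_stress$r_mm,
                              forward$interface_stress$stress_kPa,
                              xout = inv$r_mm, rule = 2)$y
  keep <- inv$r_mm <= extent - edge_margin_mm
  rel <- abs(inv$stress_kPa - fwd_on_inv) / pmax(abs(fwd_on_inv), 1e-9)
  list(max_rel_error = max(rel[keep]),
       comparison = data.frame(r_mm = inv$r_mm,
                               inverse_kPa = inv$stress_kPa,
                               forward_kPa = fwd_on_inv,
                               rel_error = rel),
       result = res)
}
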