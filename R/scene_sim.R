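#' Random phosphorescent particle field
#'
#' Draws a reproducible random field of phosphorescent microparticles over
#' the circular bottom face of the compliant layer. The particle count is
#' Poisson with mean `density_per_mm2 * pi * (layer_diameter_mm / 2)^2`;
#' positions are uniform over the disc and emission intensities uniform over
#' `intensity_range`.
#'
#' @param seed Integer RNG seed; the field is fully determined by it.
#' @param density_per_mm2 Mean particle surface density (1/mm^2). The default
#'   of 150 gives roughly ten particles inside a 35-pixel matching window at
#'   the default rig scale, a richly featured speckle pattern comparable to a
#'   dense sprinkling of sub-30 um particles.
#' @param layer_diameter_mm Layer (disc) diameter, default 19 mm.
#' @param center_mm World `c(X, Y)` position of the layer axis (mm).
#' @param intensity_range Relative emission range, within (0, 1].
#' @return Object of class `sop_particle_field` with fields `positions_mm`
#'   (n x 2 matrix of world lateral coordinates), `intensities`,
#'   `layer_diameter_mm`, `center_mm`, `seed`.
#' @export
make_particle_field <- function(seed, density_per_mm2 = 150,
                                layer_diameter_mm = 19,
                                center_mm = c(0, 0),
                                intensity_range = c(0.4, 1)) {
  if (!is.numeric(density_per_mm2) || density_per_mm2 <= 0)
    stop("invalid-argument: density_per_mm2 must be > 0")
  if (!is.numeric(layer_diameter_mm) || layer_diameter_mm <= 0)
    stop("invalid-argument: layer_diameter_mm must be > 0")
  if (intensity_range[1] <= 0 || intensity_range[2] > 1 ||
      intensity_range[1] > intensity_range[2])
    stop("invalid-argument: intensity_range must lie in (0, 1]")
  radius <- layer_diameter_mm / 2
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- max(1L, stats::rpois(1, density_per_mm2 * pi * radius^2))
  rr <- radius * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  pos <- cbind(center_mm[1] + rr * cos(th), center_mm[2] + rr * sin(th))
  structure(list(
    positions_mm = pos,
    intensities = stats::runif(n, intensity_range[1], intensity_range[2]),
    layer_diameter_mm = layer_diameter_mm,
    center_mm = center_mm,
    seed = as.integer(seed)
  ), class = "sop_particle_field")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Radially deform a particle field
#'
#' Moves every particle with the layer-bottom surface: a particle at radius
#' `r` from the layer axis is displaced radially by `ur(r)` as given by the
#' supplied radial displacement profile (linearly interpolated, flat beyond
#' the last sample).
#'
#' @param field A [make_particle_field()] object.
#' @param r_mm,ur_mm Radial displacement profile samples.
#' @return A deformed `sop_particle_field`.
#' @export
deform_particle_field <- function(field, r_mm, ur_mm) {
  stopifnot(inherits(field, "sop_particle_field"))
  dx <- field$positions_mm[, 1] - field$center_mm[1]
  dy <- field$positions_mm[, 2] - field$center_mm[2]
  r <- sqrt(dx^2 + dy^2)
  ur <- stats::approx(r_mm, ur_mm, xout = r, rule = 2)$y
  scale <- ifelse(r > 0, (r + ur) / r, 1)
  field$positions_mm <- cbind(field$center_mm[1] + dx * scale,
                              field$center_mm[2] + dy * scale)
  field
}

#' Depth field over a lateral grid
#'
#' Optical distance from the camera plane to the particle plane, sampled on
#' a rectangular lateral grid in world coordinates. Bilinear interpolation is
#' used to evaluate depth at particle positions.
#'
#' @param x_mm,y_mm Strictly increasing grid coordinate vectors (mm).
#' @param z_mm Matrix of depths, `length(y_mm)` rows x `length(x_mm)` columns.
#' @return Object of class `sop_depth_field`.
#' @export
depth_field <- function(x_mm, y_mm, z_mm) {
  z_mm <- as.matrix(z_mm)
  if (!all(dim(z_mm) == c(length(y_mm), length(x_mm))))
    stop("invalid-argument: z_mm must be length(y_mm) x length(x_mm)")
  if (any(!is.finite(z_mm)) || any(z_mm <= 0))
    stop("invalid-geometry: all depths must be finite and > 0")
  if (any(diff(x_mm) <= 0) || any(diff(y_mm) <= 0))
    stop("invalid-argument: grid coordinates must be strictly increasing")
  structure(list(x_mm = x_mm, y_mm = y_mm, z_mm = z_mm,
                 grid_pitch_mm = c(mean(diff(x_mm)), mean(diff(y_mm)))),
            class = "sop_depth_field")
}

#' Flat (optionally tilted) depth field for a given layer thickness
#'
#' Builds the depth field of a flat particle plane at layer thickness
#' `thickness_mm`, i.e. `z = z_contact + thickness`, optionally tilted about
#' the world-Y axis by `tilt_deg` (depth increases with world X).
#'
#' @param rig A [camera_rig()].
#' @param thickness_mm Layer thickness (mm, >= 0).
#' @param tilt_deg Tilt of the particle plane relative to the camera plane.
#' @param margin_mm Lateral margin beyond the cameras' combined field of view.
#' @param pitch_mm Grid pitch; the plane is affine so bilinear interpolation
#'   is exact regardless of pitch.
#' @return An `sop_depth_field`.
#' @export
flat_depth_field <- function(rig, thickness_mm, tilt_deg = 0,
                             margin_mm = 2, pitch_mm = 0.5) {
  if (thickness_mm < 0) stop("invalid-argument: thickness_mm must be >= 0")
  z0 <- rig$z_contact_mm + thickness_mm
  ov <- overlap_region(rig, z0 + 2)
  xr <- c(min(ov$x_range[1] - rig$baseline_mm, -2), ov$x_range[2] + rig$baseline_mm) +
    c(-margin_mm, margin_mm)
  yr <- ov$y_range + c(-margin_mm, margin_mm)
  x <- seq(xr[1], xr[2], by = pitch_mm)
  y <- seq(yr[1], yr[2], by = pitch_mm)
  z <- outer(rep(1, length(y)), z0 + tanpi(tilt_deg / 180) * x)
  depth_field(x, y, z)
}

#' Rendering noise model
#'
#' @param additive_sd Standard deviation of additive Gaussian read noise on
#'   the normalized [0, 1] intensity scale (default 2/255).
#' @param shot_scale If > 0, Poisson-like shot noise with variance
#'   `shot_scale * intensity` is added as Gaussian noise of that variance.
#' @param seed Integer seed making the noise reproducible.
#' @return A list of class `sop_render_noise`, or use `NULL` for noiseless
#'   rendering in oracle tests.
#' @export
render_noise <- function(additive_sd = 2 / 255, shot_scale = 0, seed = 1L) {
  structure(list(additive_sd = additive_sd, shot_scale = shot_scale,
                 seed = as.integer(seed)), class = "sop_render_noise")
}

#' Render a stereo image pair of a particle field
#'
#' Projects each particle into both rectified pinhole cameras at the optical
#' depth given by `depth`, so that a particle at depth `z` appears with
#' disparity `baseline_mm * focal_px / z` pixels. Particles are rendered as
#' isotropic Gaussian blobs of `psf_sigma_px` on a `supersample`-times finer
#' grid which is then box-averaged down, emulating defocused sub-resolution
#' particles. Optional noise is applied last, followed by quantization to
#' `bit_depth`.
#'
#' @param field A [make_particle_field()] object (positions in world mm).
#' @param depth An [depth_field()] covering the projected field of view.
#' @param rig A [camera_rig()].
#' @param psf_sigma_px Gaussian blob sigma in (full-resolution) pixels.
#' @param noise_model A [render_noise()] or `NULL` for noiseless output.
#' @param bit_depth Output quantization depth (8 or 16); 0 disables
#'   quantization (diagnostic float output).
#' @param supersample Supersampling factor (integer >= 1).
#' @param gain Peak intensity of a unit-intensity particle.
#' @param illumination_mode Recorded illumination mode tag.
#' @return Object of class `sop_stereo_pair` with `left`, `right` matrices in
#'   [0, 1] (rows = y, cols = x), `illumination_mode` and `bit_depth`.
#' @export
render_stereo_pair <- function(field, depth, rig, psf_sigma_px = 2.0,
                               noise_model = render_noise(), bit_depth = 8L,
                               supersample = 2L, gain = 0.85,
                               illumination_mode = "uv") {
  stopifnot(inherits(field, "sop_particle_field"),
            inherits(depth, "sop_depth_field"),
            inherits(rig, "sop_camera_rig"))
  if (psf_sigma_px <= 0) stop("invalid-argument: psf_sigma_px must be > 0")
  X <- field$positions_mm[, 1]
  Y <- field$positions_mm[, 2]
  # the depth grid must cover the cameras' joint field of view; particles
  # beyond the grid lie outside the view and are dropped
  zmax <- max(depth$z_mm)
  ov <- overlap_region(rig, zmax)
  fx <- c(ov$x_range[1] - rig$baseline_mm / 2,
          ov$x_range[2] + rig$baseline_mm / 2)
  if (min(depth$x_mm) > fx[1] || max(depth$x_mm) < fx[2] ||
      min(depth$y_mm) > ov$y_range[1] || max(depth$y_mm) < ov$y_range[2])
    stop("invalid-argument: depth grid does not cover the projected FOV")
  inside <- X >= min(depth$x_mm) & X <= max(depth$x_mm) &
    Y >= min(depth$y_mm) & Y <= max(depth$y_mm)
  X <- X[inside]; Y <- Y[inside]
  amp <- field$intensities[inside]
  z <- pracma::interp2(depth$x_mm, depth$y_mm, depth$z_mm, X, Y)
  if (any(!is.finite(z)))
    stop("invalid-argument: depth grid does not cover the particle field")
  if (any(z <= 0)) stop("invalid-geometry: particle behind camera plane")
  img <- lapply(c("left", "right"), function(cam) {
    p <- project_points(rig, X, Y, z, cam)
    .render_blobs(p$x, p$y, amp * gain,
                  rig$image_size_px[1], rig$image_size_px[2],
                  psf_sigma_px, as.integer(supersample))
  })
  left <- img[[1]]; right <- img[[2]]
  if (!is.null(noise_model)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(noise_model$seed)
    for (nm in c("left", "right")) {
      im <- get(nm)
      if (noise_model$additive_sd > 0)
        im <- im + stats::rnorm(length(im), 0, noise_model$additive_sd)
      if (noise_model$shot_scale > 0)
        im <- im + stats::rnorm(length(im), 0,
                                sqrt(noise_model$shot_scale * pmax(im, 0)))
      assign(nm, im)
    }
  }
  clampq <- function(im) {
    im <- pmin(pmax(im, 0), 1)
    if (bit_depth > 0) {
      lev <- 2^bit_depth - 1
      im <- round(im * lev) / lev
    }
    im
  }
  structure(list(left = clampq(left), right = clampq(right),
                 illumination_mode = illumination_mode,
                 bit_depth = as.integer(bit_depth)),
            class = "sop_stereo_pair")
}

# Gaussian blob splatting on a supersampled canvas, then box downsample.
.render_blobs <- function(px, py, amp, width, height, sigma, ss) {
  s <- max(1L, ss)
  canvas <- matrix(0, height * s, width * s)
  sig <- sigma * s
  rad <- ceiling(4 * sig)
  # full-res pixel center p maps to supersample coordinate s*(p - 0.5) + 0.5
  qx <- s * (px - 0.5) + 0.5
  qy <- s * (py - 0.5) + 0.5
  W <- width * s; H <- height * s
  keep <- qx > -rad & qx < W + rad & qy > -rad & qy < H + rad
  for (k in which(keep)) {
    cx <- qx[k]; cy <- qy[k]
    ix <- max(1L, floor(cx - rad)):min(W, ceiling(cx + rad))
    iy <- max(1L, floor(cy - rad)):min(H, ceiling(cy + rad))
    if (!length(ix) || !length(iy)) next
    gx <- exp(-((ix - cx)^2) / (2 * sig^2))
    gy <- exp(-((iy - cy)^2) / (2 * sig^2))
    canvas[iy, ix] <- canvas[iy, ix] + amp[k] * tcrossprod(gy, gx)
  }
  if (s == 1L) return(canvas)
  # box average s x s blocks
  m <- matrix(colMeans(matrix(canvas, nrow = s)), nrow = height)    # rows
  m2 <- matrix(colMeans(matrix(t(m), nrow = s)), nrow = width)      # cols
  t(m2)
}

#' @export
print.sop_stereo_pair <- function(x, ...) {
  cat(sprintf("<sop_stereo_pair> %d x %d px, %s illumination, %d-bit\n",
              ncol(x$left), nrow(x$left), x$illumination_mode, x$bit_depth))
  invisible(x)
}

#' Render a calibration stack of flat-plane compressions
#'
#' Emulates the probe's calibration protocol: the 5 mm layer compressed by a
#' flat plane parallel to (or tilted `tilt_deg` from) the imaging window at a
#' series of thicknesses, including the contact point at 0 mm where the
#' particle side is pressed directly against the window.
#'
#' @param rig A [camera_rig()].
#' @param field A [make_particle_field()].
#' @param thicknesses_mm Distinct non-negative thicknesses (mm); at least 2.
#' @param tilt_deg Plane tilt about the world-Y axis.
#' @param ... Passed to [render_stereo_pair()] (e.g. `noise_model = NULL`).
#' @return List of entries `list(thickness_mm, pair)`, ordered as given.
#' @export
make_calibration_stack <- function(rig, field, thicknesses_mm = 0:4,
                                   tilt_deg = 0, ...) {
  if (length(thicknesses_mm) < 2L)
    stop("calibration-impossible: at least 2 thicknesses are required")
  if (any(thicknesses_mm < 0))
    stop("invalid-argument: thicknesses must be non-negative")
  if (anyDuplicated(thicknesses_mm))
    stop("invalid-argument: thicknesses must be distinct")
  lapply(thicknesses_mm, function(t) {
    d <- flat_depth_field(rig, t, tilt_deg = tilt_deg)
    list(thickness_mm = t, pair = render_stereo_pair(field, d, rig, ...))
  })
}
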