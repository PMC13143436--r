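#' Stereo camera rig geometry
#'
#' Describes the probe's pair of parallel, rectified pinhole cameras. Both
#' cameras share one effective focal length (in pixel units) and identical
#' image dimensions; their optical centers are separated laterally by
#' `baseline_mm` so that a feature at optical distance `z` appears with
#' disparity `baseline_mm * focal_px / z` pixels between the two images.
#'
#' `z_contact_mm` is the *effective* pinhole object distance to the particle
#' plane when the layer is fully compressed against the imaging window
#' (thickness 0). It is an effective optical parameter: the physical path
#' from the camera plane to the window (`nominal_working_distance_mm`, kept
#' as descriptive metadata) is folded together with the camera module's
#' internal optics and the refractive path through window and layer, exactly
#' as the empirical disparity-thickness calibration does for the real probe.
#' A plane at layer thickness `t` sits at `z = z_contact_mm + t`.
#'
#' @param baseline_mm Center-to-center camera spacing (mm). Default 5.5, the
#'   probe's sensor spacing.
#' @param focal_px Effective focal length in pixel units (identical cameras).
#' @param image_size_px Integer `c(width, height)` of each camera frame.
#' @param principal_point_left,principal_point_right `c(cx, cy)` in pixel
#'   coordinates (1-based, pixel centers at integers).
#' @param z_contact_mm Effective object distance at layer thickness 0 (mm).
#' @param nominal_working_distance_mm Physical camera-plane to imaging-window
#'   distance (mm); metadata only.
#' @return An object of class `sop_camera_rig`.
#' @export
camera_rig <- function(baseline_mm = 5.5,
                       focal_px = 13800,
                       image_size_px = c(1800L, 936L),
                       principal_point_left = NULL,
                       principal_point_right = NULL,
                       z_contact_mm = 120,
                       nominal_working_distance_mm = 16) {
  if (!is.numeric(baseline_mm) || baseline_mm <= 0)
    stop("invalid-argument: baseline_mm must be > 0")
  if (!is.numeric(focal_px) || focal_px <= 0)
    stop("invalid-argument: focal_px must be > 0")
  image_size_px <- as.integer(image_size_px)
  if (length(image_size_px) != 2L || any(image_size_px < 8L))
    stop("invalid-argument: image_size_px must be c(width, height), each >= 8")
  if (z_contact_mm <= 0)
    stop("invalid-argument: z_contact_mm must be > 0")
  cc <- c((image_size_px[1] + 1) / 2, (image_size_px[2] + 1) / 2)
  if (is.null(principal_point_left)) principal_point_left <- cc
  if (is.null(principal_point_right)) principal_point_right <- cc
  inside <- function(p) p[1] >= 1 && p[1] <= image_size_px[1] &&
    p[2] >= 1 && p[2] <= image_size_px[2]
  if (!inside(principal_point_left) || !inside(principal_point_right))
    stop("invalid-argument: principal points must lie inside the image bounds")
  structure(list(
    baseline_mm = baseline_mm,
    focal_px = focal_px,
    image_size_px = image_size_px,
    principal_point_left = principal_point_left,
    principal_point_right = principal_point_right,
    z_contact_mm = z_contact_mm,
    nominal_working_distance_mm = nominal_working_distance_mm
  ), class = "sop_camera_rig")
}

#' @export
print.sop_camera_rig <- function(x, ...) {
  cat("<sop_camera_rig>\n")
  cat(sprintf("  baseline %.2f mm, focal %.0f px, image %d x %d px\n",
              x$baseline_mm, x$focal_px, x$image_size_px[1], x$image_size_px[2]))
  cat(sprintf("  effective contact distance %.1f mm (nominal working distance %.1f mm)\n",
              x$z_contact_mm, x$nominal_working_distance_mm))
  invisible(x)
}

#' Project world points into camera pixel coordinates
#'
#' World coordinates: `X` lateral (mm, along the baseline, left camera center
#' at X = 0, right camera center at X = baseline), `Y` lateral (mm, down),
#' `z` optical distance from the camera plane (mm). Pixel coordinates are
#' 1-based with x right and y down, pixel centers at integers. Disparity is
#' `x_left - x_right = baseline_mm * focal_px / z >= 0`.
#'
#' @param rig A [camera_rig()].
#' @param X,Y,z Numeric vectors of world coordinates (recycled together).
#' @param camera `"left"` or `"right"`.
#' @return A list with components `x` and `y` (pixel coordinates).
#' @export
project_points <- function(rig, X, Y, z, camera = c("left", "right")) {
  camera <- match.arg(camera)
  if (any(!is.finite(z)) || any(z <= 0))
    stop("invalid-geometry: all depths must be finite and > 0")
  if (camera == "left") {
    pp <- rig$principal_point_left
    xw <- X
  } else {
    pp <- rig$principal_point_right
    xw <- X - rig$baseline_mm
  }
  list(x = pp[1] + rig$focal_px * xw / z,
       y = pp[2] + rig$focal_px * Y / z)
}

#' Field of view limits of the overlapping stereo region
#'
#' Lateral world-X interval seen by both cameras, and the world-Y interval of
#' either camera, at optical distance `z`.
#'
#' @param rig A [camera_rig()].
#' @param z_mm Optical distance (mm).
#' @return List with `x_range`, `y_range` (mm), `width_mm`, `height_mm`,
#'   `mm_per_px`.
#' @export
overlap_region <- function(rig, z_mm) {
  f <- rig$focal_px
  w <- rig$image_size_px[1]
  h <- rig$image_size_px[2]
  s <- z_mm / f
  left_x <- c(1 - rig$principal_point_left[1], w - rig$principal_point_left[1]) * s
  right_x <- rig$baseline_mm +
    c(1 - rig$principal_point_right[1], w - rig$principal_point_right[1]) * s
  xr <- c(max(left_x[1], right_x[1]), min(left_x[2], right_x[2]))
  yr <- c(1 - rig$principal_point_left[2], h - rig$principal_point_left[2]) * s
  list(x_range = xr, y_range = yr,
       width_mm = max(0, diff(xr)), height_mm = diff(yr), mm_per_px = s)
}
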