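#' Extract a stress profile along a line
#'
#' Samples a stress map with bilinear interpolation from `center_px` along
#' `direction`, converting distance to mm with the calibrated pixel pitch.
#'
#' @param map An `sop_stress_map`.
#' @param center_px `c(x, y)` start point in the map's own pixel grid.
#' @param direction `c(dx, dy)` line direction (need not be normalized).
#' @param length_mm Profile length (mm).
#' @param cal An `sop_calibration` or a list `list(mm_per_px = c(x, y))`;
#'   defaults to the pitch stored on the map.
#' @param step_mm Sampling step; defaults to the pixel pitch.
#' @return Data frame `position_mm`, `stress_kPa`.
#' @export
extract_profile <- function(map, center_px, direction = c(1, 0), length_mm,
                            cal = NULL, step_mm = NULL) {
  stopifnot(inherits(map, "sop_stress_map"))
  mm_per_px <- if (is.null(cal)) map$mm_per_px
  else if (inherits(cal, "sop_calibration")) {
    fov_scale(cal, mean(cal$thickness_range_mm))$mm_per_px
  } else cal$mm_per_px
  if (any(!is.finite(mm_per_px)))
    stop("invalid-argument: pixel pitch unknown")
  dirn <- direction / sqrt(sum(direction^2))
  if (is.null(step_mm)) step_mm <- min(mm_per_px)
  s <- seq(0, length_mm, by = step_mm)
  xp <- center_px[1] + s * dirn[1] / mm_per_px[1]
  yp <- center_px[2] + s * dirn[2] / mm_per_px[2]
  d <- dim(map$stress_kPa)
  if (any(xp < 1 - 1e-9) || any(xp > d[2] + 1e-9) ||
      any(yp < 1 - 1e-9) || any(yp > d[1] + 1e-9))
    stop("invalid-argument: profile line exits the map")
  v <- map$stress_kPa
  v[!map$valid] <- NA
  z <- pracma::interp2(seq_len(d[2]), seq_len(d[1]), v,
                       pmin(pmax(xp, 1), d[2]), pmin(pmax(yp, 1), d[1]))
  data.frame(position_mm = s, stress_kPa = z)
}

#' Stress contrast of an inclusion
#'
#' The stress at the center of the inclusion divided by the stress in the
#' background: the center value is the mean over a 3x3-pixel disc at
#' `center_px`, the background the mean over an annulus
#' `background_radii_mm` (default 2-3 inclusion radii) around it.
#'
#' @param x An `sop_stress_map`, or a profile data frame from
#'   [extract_profile()] (columns `position_mm`, `stress_kPa`).
#' @param center_px `c(x, y)` inclusion center (map method).
#' @param mm_per_px Pixel pitch override (map method; defaults to the map's).
#' @param inclusion_radius_mm Inclusion radius used to place the background
#'   annulus.
#' @param background_radii_mm Annulus `c(inner, outer)` in mm; default
#'   `inclusion_radius_mm * c(2, 3)`.
#' @param ... Passed between methods.
#' @return Contrast ratio (dimensionless).
#' @export
stress_contrast <- function(x, ...) UseMethod("stress_contrast")

#' @rdname stress_contrast
#' @export
stress_contrast.sop_stress_map <- function(x, center_px,
                                           inclusion_radius_mm = 0.4,
                                           background_radii_mm = NULL,
                                           mm_per_px = NULL, ...) {
  if (is.null(mm_per_px)) mm_per_px <- x$mm_per_px
  if (any(!is.finite(mm_per_px)))
    stop("invalid-argument: pixel pitch unknown")
  if (is.null(background_radii_mm))
    background_radii_mm <- inclusion_radius_mm * c(2, 3)
  if (background_radii_mm[1] <= inclusion_radius_mm)
    stop("invalid-argument: background region overlaps the inclusion")
  s <- x$stress_kPa
  s[!x$valid] <- NA
  cx <- round(center_px[1]); cy <- round(center_px[2])
  d <- dim(s)
  if (cx < 2 || cx > d[2] - 1 || cy < 2 || cy > d[1] - 1)
    stop("invalid-argument: center too close to the map edge")
  center <- mean(s[cy + (-1:1), cx + (-1:1)], na.rm = TRUE)
  dx <- (rep(seq_len(d[2]), each = d[1]) - center_px[1]) * mm_per_px[1]
  dy <- (rep(seq_len(d[1]), times = d[2]) - center_px[2]) * mm_per_px[2]
  r <- sqrt(dx^2 + dy^2)
  bg <- as.vector(s)[r >= background_radii_mm[1] & r <= background_radii_mm[2]]
  if (!sum(is.finite(bg)))
    stop("invalid-argument: empty background region")
  bgm <- mean(bg, na.rm = TRUE)
  if (!is.finite(bgm) || bgm == 0)
    stop("undefined-contrast: zero background stress")
  center / bgm
}

#' @rdname stress_contrast
#' @export
stress_contrast.data.frame <- function(x, inclusion_radius_mm = 0.4,
                                       background_radii_mm = NULL, ...) {
  if (is.null(background_radii_mm))
    background_radii_mm <- inclusion_radius_mm * c(2, 3)
  p <- abs(x$position_mm)
  center <- mean(x$stress_kPa[p <= max(inclusion_radius_mm / 4,
                                       min(p) + 1e-9)], na.rm = TRUE)
  bg <- x$stress_kPa[p >= background_radii_mm[1] & p <= background_radii_mm[2]]
  if (!sum(is.finite(bg))) stop("invalid-argument: empty background region")
  bgm <- mean(bg, na.rm = TRUE)
  if (!is.finite(bgm) || bgm == 0)
    stop("undefined-contrast: zero background stress")
  center / bgm
}

#' Stress resolution from a profile (FWHM of the normalized gradient)
#'
#' Computes the central-difference gradient of the stress profile on its mm
#' axis, normalizes the gradient magnitude to unit peak, and measures the
#' full width at half maximum of the main peak by linear interpolation of
#' the half-maximum crossings.
#'
#' @param profile Data frame `position_mm`, `stress_kPa` (uniform sampling).
#' @return List of class `sop_resolution`: `fwhm_um`, `defined`, and the
#'   normalized `gradient` data frame.
#' @export
stress_resolution <- function(profile) {
  x <- profile$position_mm
  y <- profile$stress_kPa
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("invalid-argument: profile too short")
  n <- length(x)
  g <- numeric(n)
  g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  a <- abs(g)
  pk <- which.max(a)
  gn <- a / a[pk]
  cross <- function(idx) {
    # linear interpolation of the 0.5 crossing between idx and idx+1
    x[idx] + (0.5 - gn[idx]) * (x[idx + 1] - x[idx]) / (gn[idx + 1] - gn[idx])
  }
  left <- NA_real_
  for (i in seq(pk - 1, 1)) {
    if (pk == 1) break
    if (gn[i] < 0.5 && gn[i + 1] >= 0.5) { left <- cross(i); break }
  }
  right <- NA_real_
  if (pk < n) {
    for (i in seq(pk, n - 1)) {
      if (gn[i] >= 0.5 && gn[i + 1] < 0.5) { right <- cross(i); break }
    }
  }
  defined <- is.finite(left) && is.finite(right)
  structure(list(fwhm_um = if (defined) (right - left) * 1000 else NA_real_,
                 defined = defined,
                 gradient = data.frame(position_mm = x, normalized = gn)),
            class = "sop_resolution")
}

#' @export
print.sop_resolution <- function(x, ...) {
  if (x$defined) cat(sprintf("<sop_resolution> FWHM %.1f um\n", x$fwhm_um))
  else cat("<sop_resolution> undefined (no half-maximum crossings)\n")
  invisible(x)
}

#' Image-quality report for a stress map
#'
#' Bundles the two headline metrics — stress contrast over an inclusion and
#' FWHM stress resolution across its edge — together with the radial profile
#' they were computed from.
#'
#' For pixel-level noisy maps of an axisymmetric scene the lateral profile is
#' taken as the annular average around the center (identical to a line
#' profile for a noise-free axisymmetric map), lightly kernel-smoothed at
#' `smooth_sigma_px` pixels so the gradient-based resolution measures the
#' stress edge rather than pixel noise; set `radial_average = FALSE` for a
#' raw single-line profile.
#'
#' @param map An `sop_stress_map`.
#' @param center_px `c(x, y)` inclusion center.
#' @param inclusion_radius_mm Inclusion radius (mm).
#' @param profile_length_mm Length of the extracted profile.
#' @param mm_per_px Pixel pitch override.
#' @param radial_average Use the annular-average profile (default).
#' @param smooth_sigma_px Gaussian smoothing bandwidth in pixels.
#' @return List of class `sop_metrics_report`: `contrast`, `resolution_um`,
#'   `profile`, region definitions.
#' @export
metrics_report <- function(map, center_px, inclusion_radius_mm = 0.4,
                           profile_length_mm = 1.5, mm_per_px = NULL,
                           radial_average = TRUE, smooth_sigma_px = 1.5) {
  if (is.null(mm_per_px)) mm_per_px <- map$mm_per_px
  contrast <- stress_contrast(map, center_px,
                              inclusion_radius_mm = inclusion_radius_mm,
                              mm_per_px = mm_per_px)
  if (radial_average) {
    rp <- radial_profile(map$stress_kPa, map$valid, center_px, mm_per_px,
                         bin_mm = min(mm_per_px),
                         max_radius_mm = profile_length_mm + 0.2)
    s <- seq(0, profile_length_mm, by = min(mm_per_px))
    v <- .kernel_smooth_profile(rp$r_mm, rp$value, rp$n,
                                smooth_sigma_px * min(mm_per_px), s)
    prof <- data.frame(position_mm = s, stress_kPa = v)
  } else {
    prof <- extract_profile(map, center_px, c(1, 0), profile_length_mm,
                            cal = list(mm_per_px = mm_per_px))
  }
  res <- stress_resolution(prof)
  structure(list(contrast = contrast, resolution_um = res$fwhm_um,
                 resolution = res, profile = prof, center_px = center_px,
                 inclusion_radius_mm = inclusion_radius_mm,
                 background_radii_mm = inclusion_radius_mm * c(2, 3),
                 method = map$method),
            class = "sop_metrics_report")
}

#' @export
print.sop_metrics_report <- function(x, ...) {
  cat(sprintf("<sop_metrics_report> %s method: contrast %.3f, resolution %s\n",
              x$method, x$contrast,
              if (is.finite(x$resolution_um))
                sprintf("%.0f um", x$resolution_um) else "undefined"))
  invisible(x)
}
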