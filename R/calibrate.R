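#' Default field-of-view anchors
#'
#' The probe's empirically characterized overlapping field of view: 8.9 x 6.9
#' mm^2 with the layer fully compressed (0 mm) and 10.7 x 8.4 mm^2 at 4 mm
#' layer thickness. Used as the two anchor points of the linear
#' field-of-view scale model when no synthetic-rig anchors are supplied.
#'
#' @return List with `thickness_mm`, `width_mm`, `height_mm`, and (possibly
#'   `NA`) `mm_per_px_x`, `mm_per_px_y` anchor vectors.
#' @export
sop_default_fov_anchors <- function() {
  list(thickness_mm = c(0, 4), width_mm = c(8.9, 10.7),
       height_mm = c(6.9, 8.4), mm_per_px_x = c(NA_real_, NA_real_),
       mm_per_px_y = c(NA_real_, NA_real_))
}

#' Field-of-view anchors of a synthetic rig
#'
#' Computes the overlap-region extents and pixel scale of an ideal rig at two
#' anchor layer thicknesses, for use in [fit_disparity_thickness()].
#'
#' @param rig A [camera_rig()].
#' @param thickness_mm Two anchor thicknesses (default 0 and 4 mm).
#' @return Anchor list as in [sop_default_fov_anchors()].
#' @export
fov_anchors_from_rig <- function(rig, thickness_mm = c(0, 4)) {
  stopifnot(length(thickness_mm) == 2L)
  ov <- lapply(thickness_mm, function(t) overlap_region(rig, rig$z_contact_mm + t))
  list(thickness_mm = thickness_mm,
       width_mm = vapply(ov, `[[`, 0, "width_mm"),
       height_mm = vapply(ov, `[[`, 0, "height_mm"),
       mm_per_px_x = vapply(ov, `[[`, 0, "mm_per_px"),
       mm_per_px_y = vapply(ov, `[[`, 0, "mm_per_px"))
}

#' Fit the per-pixel disparity-thickness calibration
#'
#' Ordinary least-squares line of disparity (px) versus layer thickness (mm)
#' at every pixel of a stack of flat-plane disparity maps, reproducing the
#' probe's empirical characterization of the window-to-layer-bottom distance.
#' Fitting per pixel (rather than one global line) absorbs tilt between the
#' camera plane and the imaging window and residual distortion.
#'
#' @param stack List of entries `list(thickness_mm, map)` where each `map` is
#'   an [match_disparity()] result; all maps must share grid and region. At
#'   least two distinct thicknesses are required.
#' @param fov_anchors Field-of-view anchor list ([sop_default_fov_anchors()]
#'   or [fov_anchors_from_rig()]).
#' @return Object of class `sop_calibration`: per-pixel `slope_px_per_mm`,
#'   `intercept_px`, `residual_rms_px`, `valid`, the `thicknesses_mm` fitted,
#'   grid geometry (`roi`, `step`, `grid_dim`) and the `fov` model.
#' @export
fit_disparity_thickness <- function(stack, fov_anchors = sop_default_fov_anchors()) {
  th <- vapply(stack, function(s) as.numeric(s$thickness_mm), 0)
  if (length(unique(th)) < 2L)
    stop("calibration-impossible: need >= 2 distinct thicknesses")
  maps <- lapply(stack, `[[`, "map")
  dims <- lapply(maps, function(m) dim(m$disparity))
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("invalid-argument: inconsistent map dimensions in stack")
  rois <- lapply(maps, `[[`, "roi")
  if (!all(vapply(rois, identical, TRUE, rois[[1]])))
    stop("invalid-argument: inconsistent map regions in stack")
  n <- length(th)
  d <- dims[[1]]
  A <- array(NA_real_, c(d, n))
  V <- array(TRUE, c(d, n))
  for (i in seq_len(n)) {
    A[, , i] <- maps[[i]]$disparity
    V[, , i] <- maps[[i]]$valid
  }
  valid <- apply(V, c(1, 2), all)  # mask in any entry propagates
  tbar <- mean(th)
  sxx <- sum((th - tbar)^2)
  dbar <- apply(A, c(1, 2), mean)
  sxy <- matrix(0, d[1], d[2])
  for (i in seq_len(n)) sxy <- sxy + (th[i] - tbar) * (A[, , i] - dbar)
  slope <- sxy / sxx
  intercept <- dbar - slope * tbar
  ss <- matrix(0, d[1], d[2])
  for (i in seq_len(n)) ss <- ss + (A[, , i] - intercept - slope * th[i])^2
  rms <- sqrt(ss / n)
  slope[!valid] <- NA; intercept[!valid] <- NA; rms[!valid] <- NA
  sgn <- sign(slope[valid])
  if (length(sgn) && length(unique(sgn[sgn != 0])) > 1L)
    warning("calibration slopes do not share one sign across valid pixels")
  structure(list(slope_px_per_mm = slope, intercept_px = intercept,
                 residual_rms_px = rms, valid = valid,
                 thicknesses_mm = th,
                 thickness_range_mm = range(th),
                 roi = maps[[1]]$roi, step = maps[[1]]$step,
                 grid_dim = d, fov = fov_anchors),
            class = "sop_calibration")
}

#' Predicted disparity at a given thickness
#'
#' Evaluates the per-pixel calibration lines, e.g. to center the matcher's
#' search range at the expected disparity.
#'
#' @param model An [fit_disparity_thickness()] calibration.
#' @param thickness_mm Layer thickness (mm).
#' @return Matrix of predicted disparities (px) on the calibration grid.
#' @export
predict_disparity <- function(model, thickness_mm) {
  model$intercept_px + model$slope_px_per_mm * thickness_mm
}

#' Convert a disparity map to a layer thickness map
#'
#' Inverts the per-pixel linear calibration. Results are clamped to
#' `[0, max_thickness_mm + clamp_tol_mm]`; pixels farther out of range than
#' the tolerance are flagged and invalidated rather than silently clamped.
#'
#' @param model An [fit_disparity_thickness()] calibration.
#' @param disp An [match_disparity()] disparity map on the same grid.
#' @param max_thickness_mm Upper physical bound (default: the uncompressed
#'   layer thickness, taken as 5 mm when not supplied).
#' @param clamp_tol_mm Out-of-range tolerance before flagging (default 0.1).
#' @return Object of class `sop_thickness_map`: `thickness_mm`, `valid`,
#'   `flagged`, grid geometry, and the image-mean thickness.
#' @export
thickness_from_disparity <- function(model, disp, max_thickness_mm = 5,
                                     clamp_tol_mm = 0.1) {
  stopifnot(inherits(model, "sop_calibration"),
            inherits(disp, "sop_disparity_map"))
  if (!all(dim(disp$disparity) == model$grid_dim) ||
      !identical(as.integer(disp$roi), as.integer(model$roi)))
    stop("invalid-argument: disparity map grid does not match the calibration")
  zero <- is.finite(model$slope_px_per_mm) & model$slope_px_per_mm == 0
  slope <- model$slope_px_per_mm
  slope[zero] <- NA
  t <- (disp$disparity - model$intercept_px) / slope
  valid <- disp$valid & model$valid & !zero & is.finite(t)
  flagged <- valid & (t < -clamp_tol_mm | t > max_thickness_mm + clamp_tol_mm)
  t <- pmin(pmax(t, 0), max_thickness_mm + clamp_tol_mm)
  valid <- valid & !flagged
  t[!valid] <- NA
  structure(list(thickness_mm = t, valid = valid, flagged = flagged,
                 roi = disp$roi, step = disp$step,
                 mean_thickness_mm = mean(t[valid])),
            class = "sop_thickness_map")
}

#' Field-of-view scale at a given mean layer thickness
#'
#' Linear interpolation between the two calibrated anchors of the
#' overlapping field of view; the pixel scale varies almost linearly with the
#' window-to-sample distance, so a linear model is used. Values outside the
#' anchored thickness range are extrapolated and flagged.
#'
#' @param model An `sop_calibration` (its `fov` anchors are used) or an
#'   anchor list directly.
#' @param mean_thickness_mm Image-mean layer thickness (mm).
#' @return List `width_mm`, `height_mm`, `mm_per_px` (c(x, y), may be `NA`
#'   when the anchors carry no pixel scale), `extrapolated`.
#' @export
fov_scale <- function(model, mean_thickness_mm) {
  fv <- if (inherits(model, "sop_calibration")) model$fov else model
  t <- fv$thickness_mm
  lin <- function(v) v[1] + (v[2] - v[1]) * (mean_thickness_mm - t[1]) / (t[2] - t[1])
  extrap <- mean_thickness_mm < min(t) || mean_thickness_mm > max(t)
  list(width_mm = lin(fv$width_mm), height_mm = lin(fv$height_mm),
       mm_per_px = c(x = lin(fv$mm_per_px_x), y = lin(fv$mm_per_px_y)),
       extrapolated = extrap)
}

#' @export
print.sop_calibration <- function(x, ...) {
  cat(sprintf(
    "<sop_calibration> %d x %d grid, %d thicknesses (%.1f-%.1f mm), %.1f%% valid\n",
    x$grid_dim[2], x$grid_dim[1], length(x$thicknesses_mm),
    min(x$thicknesses_mm), max(x$thicknesses_mm), 100 * mean(x$valid)))
  cat(sprintf("  median slope %.3f px/mm, median |residual| %.4f px\n",
              stats::median(x$slope_px_per_mm[x$valid]),
              stats::median(x$residual_rms_px[x$valid])))
  invisible(x)
}

#' Serialize a calibration model to a .sopcal container
#'
#' Plain-text header (version, grid geometry, thickness list, field-of-view
#' anchors) followed by raw little-endian 32-bit float arrays for slope,
#' intercept and residual and a byte mask; the round trip through
#' [read_sopcal()] is bit-exact.
#'
#' @param model An `sop_calibration`.
#' @param path Output file path (conventionally `.sopcal`).
#' @return `path`, invisibly.
#' @export
write_sopcal <- function(model, path) {
  stopifnot(inherits(model, "sop_calibration"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "sopcal 1",
    paste("grid", model$grid_dim[1], model$grid_dim[2]),
    paste("roi", paste(model$roi, collapse = " ")),
    paste("step", model$step),
    paste("thicknesses", paste(format(model$thicknesses_mm, digits = 17),
                               collapse = " ")),
    paste("fov_thickness", paste(format(model$fov$thickness_mm, digits = 17),
                                 collapse = " ")),
    paste("fov_width", paste(format(model$fov$width_mm, digits = 17),
                             collapse = " ")),
    paste("fov_height", paste(format(model$fov$height_mm, digits = 17),
                              collapse = " ")),
    paste("fov_mmppx", paste(format(model$fov$mm_per_px_x, digits = 17),
                             collapse = " ")),
    paste("fov_mmppy", paste(format(model$fov$mm_per_px_y, digits = 17),
                             collapse = " ")),
    "data")
  writeLines(hdr, con)
  put <- function(m, size) {
    v <- as.vector(m)
    v[!is.finite(v)] <- NA
    writeBin(v, con, size = size, endian = "little")
  }
  put(model$slope_px_per_mm, 4L)
  put(model$intercept_px, 4L)
  put(model$residual_rms_px, 4L)
  writeBin(as.integer(model$valid), con, size = 1L)
  invisible(path)
}

#' Read a .sopcal calibration container
#'
#' @param path File written by [write_sopcal()].
#' @return An `sop_calibration`.
#' @export
read_sopcal <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("invalid-data: truncated .sopcal header")
    if (identical(ln, "data")) break
    hdr <- c(hdr, ln)
  }
  field <- function(key) {
    ln <- grep(paste0("^", key, " "), hdr, value = TRUE)
    if (!length(ln)) stop("invalid-data: missing .sopcal field ", key)
    as.numeric(strsplit(sub(paste0("^", key, " "), "", ln[1]), " +")[[1]])
  }
  if (!grepl("^sopcal 1", hdr[1])) stop("invalid-data: not a .sopcal file")
  gd <- as.integer(field("grid"))
  npx <- prod(gd)
  get <- function() {
    v <- readBin(con, numeric(), n = npx, size = 4L, endian = "little")
    matrix(v, gd[1], gd[2])
  }
  slope <- get(); intercept <- get(); rms <- get()
  valid <- matrix(readBin(con, integer(), n = npx, size = 1L) != 0L,
                  gd[1], gd[2])
  th <- field("thicknesses")
  structure(list(slope_px_per_mm = slope, intercept_px = intercept,
                 residual_rms_px = rms, valid = valid,
                 thicknesses_mm = th, thickness_range_mm = range(th),
                 roi = as.integer(field("roi")),
                 step = as.integer(field("step")[1]), grid_dim = gd,
                 fov = list(thickness_mm = field("fov_thickness"),
                            width_mm = field("fov_width"),
                            height_mm = field("fov_height"),
                            mm_per_px_x = field("fov_mmppx"),
                            mm_per_px_y = field("fov_mmppy"))),
            class = "sop_calibration")
}
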