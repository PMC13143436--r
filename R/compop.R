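#' Radial profile of a pixel map
#'
#' Averages valid pixel values in annular radius bins around a center pixel,
#' converting pixel offsets to mm with the (possibly anisotropic) pixel
#' pitch. Used to feed measured thickness maps into the axisymmetric solver.
#'
#' @param values Numeric matrix (rows = y, cols = x).
#' @param valid Logical matrix of the same size.
#' @param center_px `c(x, y)` center in the map's own pixel grid.
#' @param mm_per_px `c(x, y)` pixel pitch (mm).
#' @param bin_mm Radial bin width (mm).
#' @param max_radius_mm Optional radial cutoff.
#' @return Data frame `r_mm` (bin centers), `value`, `n`.
#' @export
radial_profile <- function(values, valid, center_px, mm_per_px,
                           bin_mm = 0.05, max_radius_mm = NULL) {
  nx <- ncol(values); ny <- nrow(values)
  dx <- (rep(seq_len(nx), each = ny) - center_px[1]) * mm_per_px[1]
  dy <- (rep(seq_len(ny), times = nx) - center_px[2]) * mm_per_px[2]
  r <- sqrt(dx^2 + dy^2)
  v <- as.vector(values)
  ok <- as.vector(valid) & is.finite(v)
  if (!is.null(max_radius_mm)) ok <- ok & r <= max_radius_mm
  b <- floor(r[ok] / bin_mm)
  agg <- tapply(v[ok], b, mean)
  cnt <- tapply(v[ok], b, length)
  data.frame(r_mm = (as.numeric(names(agg)) + 0.5) * bin_mm,
             value = as.numeric(agg), n = as.integer(cnt))
}

# count-weighted Gaussian kernel smoother for binned radial profiles
.kernel_smooth_profile <- function(r, v, n, sigma, r_out) {
  vapply(r_out, function(r0) {
    w <- n * exp(-(r - r0)^2 / (2 * sigma^2))
    sum(w * v) / sum(w)
  }, 0)
}

# revolve a radial profile into a pixel map around a center
.revolve_to_map <- function(r_mm, value, dim_yx, center_px, mm_per_px) {
  nx <- dim_yx[2]; ny <- dim_yx[1]
  dx <- (rep(seq_len(nx), each = ny) - center_px[1]) * mm_per_px[1]
  dy <- (rep(seq_len(ny), times = nx) - center_px[2]) * mm_per_px[2]
  r <- sqrt(dx^2 + dy^2)
  matrix(stats::approx(r_mm, value, xout = r, rule = 2)$y, ny, nx)
}

#' Computational optical palpation stress map
#'
#' Finite-element inversion of a measured thickness map: the layer is
#' compressed in simulation between the rigid window and a sample surface
#' moved to the measured position, and the true (Cauchy) stress where the
#' layer meets the sample is extracted. Unlike the algebraic chain this
#' accounts for friction, boundary conditions and stress redistribution
#' within the layer.
#'
#' In `"axisymmetric"` mode the radial thickness profile about `center_px`
#' is solved once and revolved back onto the pixel grid (exact for centered
#' cylindrically symmetric scenes). In `"plane_strain"` mode each image row
#' (optionally decimated) is solved independently as a plane-strain strip and
#' the rows are reassembled (an acknowledged approximation: cross-row
#' coupling is ignored).
#'
#' @param thickness An `sop_thickness_map`.
#' @param material An [layer_model()].
#' @param cal An `sop_calibration` (pixel pitch via [fov_scale()]), or a
#'   list `list(mm_per_px = c(x, y))`.
#' @param cfg An [compop_config()].
#' @param center_px `c(x, y)` center in the thickness map's own grid
#'   (axisymmetric mode).
#' @param lateral_extent_mm Layer radius/half-width to simulate; thickness
#'   outside the measured region is extrapolated flat at the edge value.
#' @param row_step Row decimation for plane-strain mode.
#' Stress is reported in the package-wide presentation convention shared
#' with [algebraic_stress_map()]: the FE interface Cauchy stress is referred
#' back to engineering measure through the measured bulk strain
#' (`sigma_E = sigma_C / lambda`) and then presented with the same
#' `(1 + eps)` factor the algebraic chain uses, so both methods' maps are
#' directly comparable pixel by pixel and coincide in the homogeneous
#' frictionless limit. The raw Cauchy interface profile remains available in
#' the attached `"profile"`.
#'
#' @return A true-measure, computational-method `sop_stress_map`; input
#'   masks are propagated. The solved interface profile is attached as
#'   attribute `"profile"` (axisymmetric mode).
#' @export
computational_stress_map <- function(thickness, material, cal,
                                     cfg = compop_config(), center_px,
                                     lateral_extent_mm = 9.5, row_step = 8L) {
  stopifnot(inherits(thickness, "sop_thickness_map"))
  mm_per_px <- if (inherits(cal, "sop_calibration"))
    fov_scale(cal, thickness$mean_thickness_mm)$mm_per_px
  else cal$mm_per_px
  if (any(!is.finite(mm_per_px)))
    stop("invalid-argument: pixel pitch unknown; supply calibrated fov anchors")
  L0 <- material$L0_mm
  dim_yx <- dim(thickness$thickness_mm)

  if (cfg$geometry_mode == "axisymmetric") {
    prof <- radial_profile(thickness$thickness_mm, thickness$valid,
                           center_px, mm_per_px, bin_mm = min(mm_per_px))
    # smooth the measured profile at the element scale before driving the
    # solver: the FE inversion amplifies pixel-scale measurement noise at
    # the interface into large spurious stress variations
    sigma <- max(cfg$element_size_mm / 2, 2 * min(mm_per_px))
    r_grid <- seq(0, max(prof$r_mm), by = min(mm_per_px))
    d_s <- .kernel_smooth_profile(prof$r_mm, prof$value, prof$n, sigma, r_grid)
    fine_r <- min(2.5, lateral_extent_mm)
    hf <- min(cfg$element_size_mm, 0.1)  # resolve the stress peak
    rb <- c(.mesh_line(0, fine_r, hf),
            .mesh_line(fine_r, lateral_extent_mm, cfg$element_size_mm,
                       3 * cfg$element_size_mm))
    mesh <- build_layer_mesh(material, lateral_extent_mm, cfg, r_breaks = rb)
    sp <- list(r_mm = r_grid, uz_mm = L0 - d_s, tangential = "friction")
    res <- tryCatch(
      solve_layer_compression(mesh, material, sp, cfg),
      sop_solver_failure = function(e) {
        # steep measured features can defeat the base increment schedule;
        # retry once with a finer one before giving up
        cfg2 <- cfg
        cfg2$load_increments <- 2L * cfg$load_increments
        solve_layer_compression(mesh, material, sp, cfg2)
      })
    ip <- interface_stress(res, mesh, "sample")
    # present in the same convention as the algebraic chain: the Cauchy
    # interface stress is referred back to engineering measure through the
    # measured uniaxial strain (sigma_E = sigma_C / lambda) and re-presented
    # with the same (1 + eps) factor, so both methods share one display
    # convention and coincide in the homogeneous limit
    eps_r <- stats::approx(r_grid, (L0 - d_s) / L0,
                           xout = ip$r_mm, rule = 2)$y
    ip$presented_kPa <- ip$stress_kPa * (1 + eps_r) / (1 - eps_r)
    smap <- .revolve_to_map(ip$r_mm, ip$presented_kPa, dim_yx, center_px,
                            mm_per_px)
    smap[!thickness$valid] <- NA
    out <- .stress_map(smap, thickness$valid, "true", "computational",
                       mm_per_px, thickness$roi, thickness$step)
    attr(out, "profile") <- ip
    attr(out, "fe_result") <- res
    return(out)
  }

  # plane-strain row-wise mode
  rows <- seq(1L, dim_yx[1], by = row_step)
  if (rows[length(rows)] != dim_yx[1]) rows <- c(rows, dim_yx[1])
  x_mm <- (seq_len(dim_yx[2]) - 1) * mm_per_px[1]
  width <- max(x_mm)
  cfg_ps <- cfg
  cfg_ps$geometry_mode <- "plane_strain"
  row_maps <- matrix(NA_real_, length(rows), dim_yx[2])
  row_ok <- logical(length(rows))
  for (i in seq_along(rows)) {
    d <- thickness$thickness_mm[rows[i], ]
    v <- thickness$valid[rows[i], ]
    if (mean(v) < 0.5) next
    dv <- stats::approx(x_mm[v], d[v], xout = x_mm, rule = 2)$y
    mesh <- build_layer_mesh(material, width, cfg_ps)
    res <- tryCatch(
      solve_layer_compression(mesh, material,
                              list(r_mm = x_mm, uz_mm = L0 - dv,
                                   tangential = "friction"),
                              cfg = cfg_ps),
      sop_solver_failure = function(e) NULL)
    if (is.null(res)) next   # row masked and logged, not fatal
    ip <- interface_stress(res, mesh, "sample")
    eps_x <- stats::approx(x_mm, (L0 - dv) / L0, xout = ip$r_mm, rule = 2)$y
    pres <- ip$stress_kPa * (1 + eps_x) / (1 - eps_x)
    row_maps[i, ] <- stats::approx(ip$r_mm, pres, xout = x_mm, rule = 2)$y
    row_ok[i] <- TRUE
  }
  if (sum(row_ok) < 2L)
    stop("solver-failure: too few rows converged in plane-strain mode")
  smap <- apply(row_maps[row_ok, , drop = FALSE], 2, function(col)
    stats::approx(rows[row_ok], col, xout = seq_len(dim_yx[1]), rule = 2)$y)
  smap[!thickness$valid] <- NA
  .stress_map(smap, thickness$valid, "true", "computational", mm_per_px,
              thickness$roi, thickness$step)
}
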