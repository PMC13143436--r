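#' Matching configuration
#'
#' Parameters of the windowed disparity matcher. The full-resolution mode
#' uses a 35-pixel-diameter circular window centered on every processed
#' pixel; live mode processes every `decimation`-th pixel with the smaller
#' `live_window_px` window.
#'
#' @param window_diameter_px Odd window diameter >= 3 (default 35).
#' @param search_halfwidth_px Integer half-width of the disparity search
#'   range around the predicted center (default 40).
#' @param decimation Grid decimation factor (1 = full resolution).
#' @param live_window_px Odd window diameter for live/decimated mode.
#' @param normalization `"zncc"` for zero-mean SSD scaled by the window
#'   norms (invariant to affine intensity changes), or `"ssd"` for plain SSD
#'   over left-window energy.
#' @return Object of class `sop_match_config`.
#' @export
match_config <- function(window_diameter_px = 35L, search_halfwidth_px = 40L,
                         decimation = 1L, live_window_px = 17L,
                         normalization = c("zncc", "ssd")) {
  normalization <- match.arg(normalization)
  window_diameter_px <- as.integer(window_diameter_px)
  live_window_px <- as.integer(live_window_px)
  if (window_diameter_px < 3L || window_diameter_px %% 2L == 0L)
    stop("invalid-argument: window diameter must be odd and >= 3")
  if (live_window_px < 3L || live_window_px %% 2L == 0L)
    stop("invalid-argument: live window diameter must be odd and >= 3")
  if (search_halfwidth_px < 1L)
    stop("invalid-argument: search halfwidth must be >= 1")
  if (decimation < 1L)
    stop("invalid-argument: decimation must be >= 1")
  structure(list(window_diameter_px = window_diameter_px,
                 search_halfwidth_px = as.integer(search_halfwidth_px),
                 decimation = as.integer(decimation),
                 live_window_px = live_window_px,
                 normalization = normalization),
            class = "sop_match_config")
}

# circular window offsets: integer pixels within radius diameter/2 of the
# center, ordered dy-fastest so window reads walk down contiguous columns
# of the column-major image matrices
.window_offsets <- function(diameter_px) {
  r <- diameter_px / 2
  k <- floor(r)
  g <- expand.grid(dy = -k:k, dx = -k:k)
  g <- g[g$dx^2 + g$dy^2 <= r^2, ]
  list(dx = as.integer(g$dx), dy = as.integer(g$dy))
}

#' Sub-pixel disparity refinement by quadratic vertex fit
#'
#' Fits a parabola through the cost at the discrete minimum and its two
#' neighbours and returns the vertex offset
#' `delta = (c_minus - c_plus) / (2 (c_minus - 2 c_0 + c_plus))`, clamped to
#' (-1, 1). A non-positive curvature yields offset 0 with a degenerate flag.
#'
#' @param cost_minus,cost_0,cost_plus Costs at displacement -1, 0, +1 around
#'   the discrete minimum (`cost_0 <= min(cost_minus, cost_plus)` required).
#' @return List with `offset` and logical `degenerate`.
#' @export
subpixel_refine <- function(cost_minus, cost_0, cost_plus) {
  if (!all(is.finite(c(cost_minus, cost_0, cost_plus))))
    stop("invalid-argument: costs must be finite")
  if (cost_0 > min(cost_minus, cost_plus) + 1e-12 * max(1, abs(cost_0)))
    stop("invalid-argument: cost_0 must be the discrete minimum")
  denom <- cost_minus - 2 * cost_0 + cost_plus
  if (denom <= 0) return(list(offset = 0, degenerate = TRUE))
  offset <- (cost_minus - cost_plus) / (2 * denom)
  offset <- max(min(offset, 1 - 1e-9), -(1 - 1e-9))
  list(offset = offset, degenerate = FALSE)
}

#' Per-pixel disparity map between rectified stereo images
#'
#' For every processed pixel of the left image a normalized least-squares
#' difference cost is evaluated against candidate window centers in the right
#' image over `center +/- search_halfwidth_px`; the integer minimum (ties
#' broken toward the smaller disparity) is refined with [subpixel_refine()].
#' Pixels whose window exits the image, whose window is constant, or whose
#' cost minimum lies on the search boundary are masked.
#'
#' @param pair An [render_stereo_pair()] object or a list with `left`/`right`
#'   matrices of identical dimensions.
#' @param cfg A [match_config()].
#' @param center Predicted disparity (pixels): a scalar, or a matrix matching
#'   the processed output grid (e.g. a calibration-model prediction).
#' @param roi Processed region `c(x0, x1, y0, y1)` in left-image pixel
#'   coordinates (inclusive); default: the largest region whose windows stay
#'   inside the image.
#' @param step Processing stride (internal; use [match_live()] for the
#'   decimated live mode).
#' @param window_diameter_px Window override (internal).
#' @return Object of class `sop_disparity_map`: `disparity` (sub-pixel, px),
#'   `valid`, `cost`, `degenerate`, `roi`, `step`, `window_diameter_px`,
#'   `search_range`.
#' @export
match_disparity <- function(pair, cfg = match_config(), center, roi = NULL,
                            step = 1L, window_diameter_px = NULL) {
  left <- pair$left; right <- pair$right
  if (!all(dim(left) == dim(right)))
    stop("invalid-argument: left and right images must have identical size")
  wd <- if (is.null(window_diameter_px)) cfg$window_diameter_px else
    as.integer(window_diameter_px)
  off <- .window_offsets(wd)
  k <- max(abs(c(off$dx, off$dy)))
  W <- ncol(left); H <- nrow(left)
  if (is.null(roi)) roi <- c(1L + k, W - k, 1L + k, H - k)
  roi <- as.integer(roi)
  if (roi[1] < 1L + k || roi[2] > W - k || roi[3] < 1L + k || roi[4] > H - k)
    stop("invalid-argument: roi windows exit the image")
  if (roi[2] < roi[1] || roi[4] < roi[3])
    stop("invalid-argument: empty roi")
  if (cfg$search_halfwidth_px < 1L)
    stop("invalid-argument: search range empty")
  nx <- (roi[2] - roi[1]) %/% step + 1L
  ny <- (roi[4] - roi[3]) %/% step + 1L
  if (is.matrix(center)) {
    if (!all(dim(center) == c(ny, nx)))
      stop("invalid-argument: center matrix must match the output grid")
    cm <- center
  } else {
    cm <- matrix(as.numeric(center[1]), 1, 1)
  }
  res <- .match_core_cpp(left, right, roi, as.integer(step),
                         off$dx, off$dy, cm,
                         as.integer(cfg$search_halfwidth_px),
                         if (cfg$normalization == "zncc") 0L else 1L, 1e-12)
  structure(list(disparity = res$disparity, valid = res$valid,
                 cost = res$cost, degenerate = res$degenerate,
                 roi = roi, step = as.integer(step),
                 window_diameter_px = wd,
                 search_range = c(-cfg$search_halfwidth_px,
                                  cfg$search_halfwidth_px),
                 decimated = step > 1L, grid_pitch_px = as.integer(step)),
            class = "sop_disparity_map")
}

#' Live-mode (decimated) disparity map
#'
#' Processes every `decimation`-th pixel in x and y with the smaller live
#' window, as used for video-rate display while acquiring data.
#'
#' @inheritParams match_disparity
#' @return An `sop_disparity_map` flagged as decimated with its grid pitch.
#' @export
match_live <- function(pair, cfg = match_config(decimation = 2L), center,
                       roi = NULL) {
  if (cfg$decimation < 2L)
    stop("invalid-argument: live mode requires decimation >= 2")
  match_disparity(pair, cfg, center, roi = roi, step = cfg$decimation,
                  window_diameter_px = cfg$live_window_px)
}

#' Upsample a decimated disparity map to the full pixel grid
#'
#' Bilinear interpolation of the decimated grid back to every pixel of its
#' region of interest, so live-mode maps can feed the downstream
#' thickness/stress chain.
#'
#' @param map A decimated `sop_disparity_map`.
#' @return A full-resolution `sop_disparity_map` (interpolated pixels are
#'   valid where all surrounding decimated samples were valid).
#' @export
upsample_disparity <- function(map) {
  stopifnot(inherits(map, "sop_disparity_map"))
  if (map$step == 1L) return(map)
  xs <- seq(map$roi[1], map$roi[2], by = map$step)
  ys <- seq(map$roi[3], map$roi[4], by = map$step)
  xo <- seq(map$roi[1], map$roi[1] + (length(xs) - 1L) * map$step)
  yo <- seq(map$roi[3], map$roi[3] + (length(ys) - 1L) * map$step)
  d <- map$disparity
  dv <- d; dv[!map$valid] <- NA
  # fill isolated invalids with neighbour means so interpolation stays finite
  fill <- mean(dv, na.rm = TRUE)
  dv[is.na(dv)] <- fill
  gx <- pracma::meshgrid(xo, yo)
  di <- pracma::interp2(xs, ys, dv, as.vector(gx$X), as.vector(gx$Y))
  vi <- pracma::interp2(xs, ys, matrix(as.numeric(map$valid), nrow(d)),
                        as.vector(gx$X), as.vector(gx$Y))
  dm <- matrix(di, length(yo), length(xo))
  vm <- matrix(vi >= 1 - 1e-9, length(yo), length(xo))
  structure(list(disparity = dm, valid = vm,
                 cost = matrix(NA_real_, length(yo), length(xo)),
                 degenerate = matrix(FALSE, length(yo), length(xo)),
                 roi = c(xo[1], xo[length(xo)], yo[1], yo[length(yo)]),
                 step = 1L, window_diameter_px = map$window_diameter_px,
                 search_range = map$search_range,
                 decimated = FALSE, grid_pitch_px = 1L),
            class = "sop_disparity_map")
}

#' Cost curve diagnostics at one pixel
#'
#' Exhaustive evaluation of the matching cost over a candidate disparity
#' range at a single left-image pixel.
#'
#' @inheritParams match_disparity
#' @param x,y Pixel coordinates in the left image.
#' @param candidates Integer candidate disparities.
#' @return Numeric vector of costs (NA where the candidate window exits the
#'   image).
#' @export
match_cost_curve <- function(pair, x, y, candidates, cfg = match_config(),
                             window_diameter_px = NULL) {
  wd <- if (is.null(window_diameter_px)) cfg$window_diameter_px else
    as.integer(window_diameter_px)
  off <- .window_offsets(wd)
  .match_cost_curve_cpp(pair$left, pair$right, as.integer(x), as.integer(y),
                        off$dx, off$dy, as.integer(candidates),
                        if (cfg$normalization == "zncc") 0L else 1L, 1e-12)
}

#' @export
print.sop_disparity_map <- function(x, ...) {
  cat(sprintf(
    "<sop_disparity_map> %d x %d grid (step %d), window %d px, %.1f%% valid\n",
    ncol(x$disparity), nrow(x$disparity), x$step, x$window_diameter_px,
    100 * mean(x$valid)))
  invisible(x)
}
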