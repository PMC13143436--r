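#' Stiff-inclusion phantom specification
#'
#' Geometry and moduli of the structured silicone phantom used to quantify
#' imaging performance: a soft cylindrical background containing a stiff
#' cylindrical inclusion just below the surface. Defaults reproduce the
#' probe's benchmark phantom: 35 mm diameter x 3.5 mm, with a 0.8 mm
#' diameter x 2 mm inclusion 0.3 mm below the surface, ~900 kPa inclusion in
#' a ~15 kPa background (tangent moduli; converted to Neo-Hookean `C10` via
#' `E = 6 C10`).
#'
#' @param phantom_diameter_mm,phantom_thickness_mm Background cylinder.
#' @param inclusion_diameter_mm,inclusion_thickness_mm Inclusion cylinder.
#' @param inclusion_depth_below_surface_mm Depth of the inclusion top below
#'   the phantom surface.
#' @param background_modulus_kPa,inclusion_modulus_kPa Young's moduli (kPa).
#' @return Object of class `sop_phantom_spec`.
#' @export
phantom_spec <- function(phantom_diameter_mm = 35,
                         phantom_thickness_mm = 3.5,
                         inclusion_diameter_mm = 0.8,
                         inclusion_thickness_mm = 2,
                         inclusion_depth_below_surface_mm = 0.3,
                         background_modulus_kPa = 15,
                         inclusion_modulus_kPa = 900) {
  v <- c(phantom_diameter_mm, phantom_thickness_mm, inclusion_diameter_mm,
         inclusion_thickness_mm, inclusion_depth_below_surface_mm,
         background_modulus_kPa, inclusion_modulus_kPa)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("invalid-argument: all phantom dimensions and moduli must be > 0")
  if (inclusion_thickness_mm + inclusion_depth_below_surface_mm >
      phantom_thickness_mm ||
      inclusion_diameter_mm >= phantom_diameter_mm)
    stop("invalid-argument: inclusion must fit entirely inside the phantom")
  structure(list(phantom_diameter_mm = phantom_diameter_mm,
                 phantom_thickness_mm = phantom_thickness_mm,
                 inclusion_diameter_mm = inclusion_diameter_mm,
                 inclusion_thickness_mm = inclusion_thickness_mm,
                 inclusion_depth_below_surface_mm = inclusion_depth_below_surface_mm,
                 background_modulus_kPa = background_modulus_kPa,
                 inclusion_modulus_kPa = inclusion_modulus_kPa),
            class = "sop_phantom_spec")
}

#' Forward finite-element model of the layer-on-phantom compression
#'
#' Axisymmetric ground-truth simulation of the benchmark experiment: the
#' compliant layer on top of the inclusion phantom, compressed by the rigid
#' imaging window until the layer's area-mean engineering strain reaches
#' `target_mean_strain` (window displacement adjusted by secant iteration).
#' Returns the revolved layer-bottom thickness profile and the true
#' interface axial stress profile, the ground truth against which the
#' algebraic and computational stress maps are benchmarked.
#'
#' @param phantom A [phantom_spec()].
#' @param layer An [layer_model()].
#' @param target_mean_strain Area-mean layer strain to reach (0, 0.6).
#' @param cfg An [compop_config()] (axisymmetric mode required).
#' @param strain_tol Relative tolerance on the achieved mean strain.
#' @param interface Layer-phantom interface condition: `"bonded"` (default)
#'   or lubricated `"friction"` contact (duplicated-node normal tie with
#'   pair-wise Coulomb friction; cannot represent contact separation).
#' @return List of class `sop_forward_model`: `thickness` (data frame
#'   `R0_mm`, `r_mm` deformed, `d_mm`, `ur_mm`, `uz_mm`), `interface_stress`
#'   profile, the FE `result` and `mesh`, window displacement `delta_mm` and
#'   achieved `mean_strain`.
#' @export
phantom_forward_model <- function(phantom, layer, target_mean_strain = 0.4,
                                  cfg = compop_config(), strain_tol = 0.02,
                                  interface = c("bonded", "friction")) {
  interface <- match.arg(interface)
  if (target_mean_strain <= 0 || target_mean_strain >= 0.6)
    stop("invalid-argument: target_mean_strain must be in (0, 0.6)")
  if (cfg$geometry_mode != "axisymmetric")
    stop("invalid-argument: the forward phantom model is axisymmetric")
  mesh <- build_phantom_mesh(phantom, layer, cfg, interface = interface)
  L0 <- layer$L0_mm
  Hp <- phantom$phantom_thickness_mm

  solve_delta <- function(delta) {
    win <- mesh$sets$window
    base <- mesh$sets$base
    # base bonded to its support plate; friction applies at the probe window
    # and (for the lubricated interface variant) between layer and phantom
    bc <- data.frame(dof = 2L * win, value = -delta)
    bc <- rbind(bc, data.frame(dof = 2L * base, value = 0))
    bc <- rbind(bc, data.frame(dof = 2L * base - 1L, value = 0))
    bc <- rbind(bc, data.frame(dof = 2L * mesh$sets$axis - 1L, value = 0))
    bc <- bc[!duplicated(bc$dof), ]
    friction <- list()
    if (cfg$friction_coefficient > 0)
      friction <- list(
        .friction_group(mesh, "window", mesh$materials$layer, cfg))
    if (!is.null(mesh$sets$interface_pairs))
      friction <- c(friction,
                    list(.pair_friction_group(mesh, mesh$materials$layer, cfg)))
    tryCatch(.fem_solve(mesh, cfg, bc, friction),
             sop_solver_failure = function(e) {
               # retry once with a finer increment schedule: the inclusion
               # corner concentrates extreme distortion at fine meshes
               cfg2 <- cfg
               cfg2$load_increments <- 2L * cfg$load_increments
               .fem_solve(mesh, cfg2, bc, friction)
             })
  }

  mean_strain_of <- function(res, delta) {
    int <- mesh$sets$interface
    r <- mesh$nodes[int, 1]
    o <- order(r)
    r <- r[o]
    uz <- res$u[2L * int][o]
    d <- L0 - delta - uz
    eps <- (L0 - d) / L0
    w <- if (mesh$mode == "axisymmetric") r else rep(1, length(r))
    # trapezoid area-weighted mean over the layer radius
    sum(diff(r) * (eps[-1] * w[-1] + eps[-length(r)] * w[-length(r)]) / 2) /
      sum(diff(r) * (w[-1] + w[-length(r)]) / 2)
  }

  # initial guess: layer in series with the (bonded-base, near-confined)
  # phantom; the phantom compresses per its oedometric modulus
  sig <- neo_hookean_stress(target_mean_strain, layer$C10_kPa)
  nu <- layer$poisson_ratio
  M_p <- phantom$background_modulus_kPa * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
  d1 <- target_mean_strain * L0 + min(sig / M_p, 0.5) * Hp
  r1 <- solve_delta(d1)
  e1 <- mean_strain_of(r1, d1)
  it <- 0
  d0 <- 0; e0 <- 0
  res <- r1; delta <- d1
  while (abs(e1 - target_mean_strain) > strain_tol * target_mean_strain &&
         it < 8) {
    d2 <- d1 + (target_mean_strain - e1) * (d1 - d0) / (e1 - e0)
    r2 <- tryCatch(solve_delta(d2), sop_solver_failure = function(e) NULL)
    if (is.null(r2)) {            # overshoot: bisect back toward last good
      d2 <- (d1 + d2) / 2
      r2 <- solve_delta(d2)
    }
    d0 <- d1; e0 <- e1
    d1 <- d2
    res <- r2
    e1 <- mean_strain_of(res, d1)
    delta <- d1
    it <- it + 1
  }
  res <- if (it == 0) r1 else res
  delta <- d1

  int <- mesh$sets$interface
  r0 <- mesh$nodes[int, 1]
  o <- order(r0)
  int <- int[o]; r0 <- r0[o]
  ur <- res$u[2L * int - 1L]
  uz <- res$u[2L * int]
  d <- L0 - delta - uz
  thick <- data.frame(R0_mm = r0, r_mm = r0 + ur, d_mm = d,
                      ur_mm = ur, uz_mm = uz)

  # interface stress: extrapolated from the layer-side elements above Hp
  lay <- mesh
  prof <- .interface_profile_at(res, mesh, z_ref = Hp, from_above = TRUE)
  structure(list(thickness = thick, interface_stress = prof,
                 result = res, mesh = lay, delta_mm = delta,
                 mean_strain = e1, secant_iterations = it),
            class = "sop_forward_model")
}

# stress profile on an interior horizontal material line (reference height
# z_ref), extrapolated from the Gauss rows of the elements just above (or
# below) it.
.interface_profile_at <- function(result, mesh, z_ref, from_above = TRUE) {
  gp <- as.data.frame(result$gp_stress)
  el_z <- matrix(mesh$nodes[t(mesh$elems), 2], ncol = 4, byrow = TRUE)
  if (from_above) {
    on_b <- which(abs(apply(el_z, 1, min) - z_ref) < 1e-9)
  } else {
    on_b <- which(abs(apply(el_z, 1, max) - z_ref) < 1e-9)
  }
  rows <- gp[gp$elem %in% on_b, , drop = FALSE]
  out <- do.call(rbind, lapply(split(rows, rows$elem), function(df) {
    lo <- if (from_above) c(1, 2) else c(4, 3)
    hi <- if (from_above) c(4, 3) else c(1, 2)
    a <- (1 + sqrt(3)) / 2
    b <- (1 - sqrt(3)) / 2
    data.frame(r_mm = a * df$r[lo] + b * df$r[hi],
               R0_mm = a * df$R0[lo] + b * df$R0[hi],
               stress_kPa = -(a * df$s_zz[lo] + b * df$s_zz[hi]),
               s_rr_kPa = -(a * df$s_rr[lo] + b * df$s_rr[hi]),
               eng_stress_kPa = -(a * (df$s_zz * df$Frr * df$Ftt)[lo] +
                                  b * (df$s_zz * df$Frr * df$Ftt)[hi]))
  }))
  out <- out[order(out$r_mm), ]
  rownames(out) <- NULL
  out
}

#' @export
print.sop_forward_model <- function(x, ...) {
  cat(sprintf(
    "<sop_forward_model> window displacement %.3f mm, mean layer strain %.3f\n",
    x$delta_mm, x$mean_strain))
  cat(sprintf("  interface stress %.2f-%.2f kPa over r 0-%.1f mm\n",
              min(x$interface_stress$stress_kPa),
              max(x$interface_stress$stress_kPa),
              max(x$interface_stress$r_mm)))
  invisible(x)
}
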