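# Incremental Newton solver for the large-deformation Neo-Hookean model.
#
# Dirichlet constraints are imposed by elimination and scaled by the load
# factor. Friction at rigid contact surfaces is a smooth pseudo-elastic
# regularization of the Coulomb law: the tangential nodal force is
#   F_t = -mu p tanh(u_t / s_el)
# with the nodal normal reaction magnitude p lagged from the previously
# converged increment (the first increment is frictionless) and a fixed,
# mesh-independent elastic-slip distance s_el.

# bc: data.frame(dof, value) — total prescribed displacement at load factor 1
# friction: list of groups: list(t_dof, n_dof, s_el, mu); all vectors aligned
.fem_solve <- function(mesh, cfg, bc, friction = list(),
                       tol = cfg$newton_tolerance) {
  nodes <- mesh$nodes
  elems <- mesh$elems
  ndof <- 2L * nrow(nodes)
  C10 <- vapply(mesh$materials, `[[`, 0, "C10_kPa")[mesh$material_id]
  Kb <- vapply(mesh$materials, fe_bulk_modulus, 0)[mesh$material_id]
  axisym <- mesh$mode == "axisymmetric"

  cdof <- bc$dof
  if (anyDuplicated(cdof)) stop("invalid-argument: duplicate constrained dofs")
  cval <- bc$value
  free <- setdiff(seq_len(ndof), cdof)

  # contact groups: "rigid" (friction against a fixed rigid plane, normal
  # handled by Dirichlet) and "pair" (duplicated-node interface: stiff
  # normal penalty tie + tangential friction on the relative slip)
  for (i in seq_along(friction))
    if (is.null(friction[[i]]$type)) friction[[i]]$type <- "rigid"
  has_fr <- length(friction) > 0
  p_bar <- lapply(friction, function(g)
    numeric(length(if (g$type == "rigid") g$t_dof else g$t_dof_a)))

  u <- numeric(ndof)
  t_now <- 0
  dt0 <- 1 / cfg$load_increments
  dt <- dt0
  hist <- list()
  force_scale <- 1e-8

  # regularized Coulomb: traction saturates at mu*p over the fixed elastic
  # slip distance s_el, independent of the mesh
  tanh_fric <- function(s, cap, s_el) {
    f <- numeric(length(s))
    k <- numeric(length(s))
    act <- cap > 0
    x <- s / s_el
    f[act] <- -cap[act] * tanh(x[act])
    k[act] <- (cap[act] / s_el) / cosh(pmin(abs(x[act]), 30))^2
    list(f = f, k = k)
  }

  # contact residual forces (added to fint) and stiffness triplets
  contact_terms <- function(uvec, want_k = TRUE) {
    f <- numeric(ndof)
    ti <- integer(0); tj <- integer(0); tv <- numeric(0)
    for (gi in seq_along(friction)) {
      g <- friction[[gi]]
      if (g$type == "rigid") {
        fr <- tanh_fric(uvec[g$t_dof], g$mu * p_bar[[gi]], g$s_el)
        f[g$t_dof] <- f[g$t_dof] - fr$f
        if (want_k) {
          ti <- c(ti, g$t_dof); tj <- c(tj, g$t_dof); tv <- c(tv, fr$k)
        }
      } else {
        ften <- g$k_n * (uvec[g$n_dof_a] - uvec[g$n_dof_b])
        f[g$n_dof_a] <- f[g$n_dof_a] + ften
        f[g$n_dof_b] <- f[g$n_dof_b] - ften
        fr <- tanh_fric(uvec[g$t_dof_a] - uvec[g$t_dof_b],
                        g$mu * p_bar[[gi]], g$s_el)
        f[g$t_dof_a] <- f[g$t_dof_a] - fr$f
        f[g$t_dof_b] <- f[g$t_dof_b] + fr$f
        if (want_k) {
          ti <- c(ti, g$n_dof_a, g$n_dof_b, g$n_dof_a, g$n_dof_b,
                  g$t_dof_a, g$t_dof_b, g$t_dof_a, g$t_dof_b)
          tj <- c(tj, g$n_dof_a, g$n_dof_b, g$n_dof_b, g$n_dof_a,
                  g$t_dof_a, g$t_dof_b, g$t_dof_b, g$t_dof_a)
          tv <- c(tv, g$k_n, g$k_n, -g$k_n, -g$k_n,
                  fr$k, fr$k, -fr$k, -fr$k)
        }
      }
    }
    list(f = f, ti = ti, tj = tj, tv = tv)
  }

  update_p_bar <- function(uvec, fint) {
    for (gi in seq_along(friction)) {
      g <- friction[[gi]]
      p_bar[[gi]] <<- if (g$type == "rigid") abs(fint[g$n_dof])
      else abs(g$k_n * (uvec[g$n_dof_a] - uvec[g$n_dof_b]))
    }
  }

  residual_at <- function(uvec) {
    a <- .fem_assemble_cpp(nodes, elems, uvec, C10, Kb, axisym, FALSE)
    if (a$Jmin <= 0) return(list(ok = FALSE))
    r <- a$fint
    if (has_fr) r <- r + contact_terms(uvec, want_k = FALSE)$f
    list(ok = TRUE, rnorm = sqrt(sum(r[free]^2)))
  }

  newton_at <- function(ut) {
    converged <- FALSE
    res_hist <- numeric(0)
    for (it in seq_len(cfg$max_newton_iterations)) {
      asm <- .fem_assemble_cpp(nodes, elems, ut, C10, Kb, axisym, TRUE)
      if (asm$Jmin <= 0) break
      r <- asm$fint
      ct <- if (has_fr) contact_terms(ut) else NULL
      if (has_fr) r <- r + ct$f
      rnorm <- sqrt(sum(r[free]^2))
      ref <- max(sqrt(sum(asm$fint[cdof]^2)), force_scale)
      res_hist <- c(res_hist, rnorm / ref)
      if (rnorm <= tol * ref) { converged <- TRUE; break }
      K <- Matrix::sparseMatrix(i = asm$ti, j = asm$tj, x = asm$tv,
                                dims = c(ndof, ndof))
      if (has_fr && length(ct$ti))
        K <- K + Matrix::sparseMatrix(i = ct$ti, j = ct$tj, x = ct$tv,
                                      dims = c(ndof, ndof))
      du <- tryCatch(
        as.numeric(Matrix::solve(K[free, free, drop = FALSE], -r[free])),
        error = function(e) NULL)
      if (is.null(du) || any(!is.finite(du))) break
      # backtracking line search: avoid element inversion and require a
      # residual decrease; near-singular corners otherwise cause overshoot
      alpha <- 1
      cand <- NULL
      repeat {
        trial <- ut
        trial[free] <- trial[free] + alpha * du
        rr <- residual_at(trial)
        if (rr$ok && rr$rnorm < rnorm * (1 - 1e-4 * alpha)) {
          cand <- trial
          break
        }
        if (alpha <= 1 / 16) {
          if (rr$ok) cand <- trial  # accept a non-inverting step and go on
          break
        }
        alpha <- alpha / 2
      }
      if (is.null(cand)) break
      ut <- cand
    }
    list(u = ut, converged = converged, iterations = it,
         residuals = res_hist)
  }

  while (t_now < 1 - 1e-12) {
    t_try <- min(t_now + dt, 1)
    ut <- u
    ut[cdof] <- t_try * cval
    nw <- newton_at(ut)
    hist[[length(hist) + 1]] <- list(t = t_try, iterations = nw$iterations,
                                     residuals = nw$residuals,
                                     converged = nw$converged)
    if (nw$converged) {
      u <- nw$u
      t_now <- t_try
      dt <- min(dt * 1.5, dt0)
      if (has_fr) {
        asm <- .fem_assemble_cpp(nodes, elems, u, C10, Kb, axisym, FALSE)
        update_p_bar(u, asm$fint)
      }
    } else {
      dt <- dt / 2
      if (dt < dt0 / 64 - 1e-15)
        stop(structure(class = c("sop_solver_failure", "error", "condition"),
                       list(message = paste0(
                         "solver-failure: no convergence at load factor ",
                         signif(t_try, 4), " (min increment reached)"),
                         call = sys.call(-1), history = hist)))
    }
  }

  # friction self-consistency polish: re-equilibrate at full load with the
  # contact pressure updated from the current state until it stabilizes, so
  # the converged solution does not depend on the increment schedule
  if (has_fr) {
    for (pol in seq_len(10)) {
      asm <- .fem_assemble_cpp(nodes, elems, u, C10, Kb, axisym, FALSE)
      p_old <- unlist(p_bar)
      update_p_bar(u, asm$fint)
      p_new <- unlist(p_bar)
      if (max(abs(p_new - p_old)) <= 0.002 * max(p_new, 1e-12)) break
      nw <- newton_at(u)
      if (!nw$converged) {  # keep the last consistent state
        p_bar <- utils::relist(p_old, p_bar)
        break
      }
      u <- nw$u
      hist[[length(hist) + 1]] <- list(t = 1, iterations = nw$iterations,
                                       residuals = nw$residuals,
                                       converged = TRUE, polish = TRUE)
    }
  }

  asm <- .fem_assemble_cpp(nodes, elems, u, C10, Kb, axisym, FALSE)
  gp <- .fem_stress_cpp(nodes, elems, u, C10, Kb, axisym)
  structure(list(u = u, nodes = nodes, elems = elems,
                 gp_stress = gp, J_range = range(gp[, "J"]),
                 reactions = asm$fint,
                 friction = list(groups = friction, p_bar = p_bar),
                 history = hist, converged = TRUE,
                 final_residual = utils::tail(hist, 1)[[1]]$residuals),
            class = "sop_fe_result")
}

#' @export
print.sop_fe_result <- function(x, ...) {
  cat(sprintf("<sop_fe_result> %d dofs, %d increments, J in [%.4f, %.4f]\n",
              length(x$u), length(x$history), x$J_range[1], x$J_range[2]))
  invisible(x)
}

# friction group for a set of contact nodes against a rigid plane:
# tangential dof = radial, normal dof = axial; the Coulomb cap comes from
# the lagged nodal normal reaction, the stick regime from the configured
# elastic-slip distance.
.friction_group <- function(mesh, node_set, material, cfg) {
  nodes <- mesh$sets[[node_set]]
  r <- mesh$nodes[nodes, 1]
  o <- order(r)
  nodes <- nodes[o]
  list(type = "rigid", t_dof = 2L * nodes - 1L, n_dof = 2L * nodes,
       s_el = cfg$elastic_slip_mm, mu = cfg$friction_coefficient)
}

# duplicated-node interface group: stiff normal penalty tie plus tangential
# regularized Coulomb friction on the relative slip of each node pair
.pair_friction_group <- function(mesh, material, cfg, penalty_scale = 20) {
  pr <- mesh$sets$interface_pairs
  a <- pr[, 1]; b <- pr[, 2]
  r <- mesh$nodes[a, 1]
  o <- order(r)
  a <- a[o]; b <- b[o]; r <- r[o]
  h <- diff(r)
  trib <- c(h / 2, 0) + c(0, h / 2)
  area <- if (mesh$mode == "axisymmetric") 2 * pi * pmax(r, h[1] / 4) * trib
          else trib
  h_elem <- mean(h)
  kn_per_area <- penalty_scale * fe_bulk_modulus(material) / h_elem
  list(type = "pair",
       t_dof_a = 2L * a - 1L, t_dof_b = 2L * b - 1L,
       n_dof_a = 2L * a, n_dof_b = 2L * b,
       s_el = cfg$elastic_slip_mm, k_n = kn_per_area * area,
       mu = cfg$friction_coefficient)
}

#' Solve compression of the layer against a measured sample surface
#'
#' Computational optical palpation's core inversion: the layer is compressed
#' between the rigid imaging window (top, held in place with frictional
#' tangential contact) and the sample surface (bottom), which is driven to
#' the measured position. The sample-side boundary condition is either
#' `"normal_friction"` (normal displacement prescribed from the measured
#' thickness, tangential motion governed by regularized Coulomb friction —
#' the default, matching what can be measured) or `"prescribed"` (both
#' displacement components imposed, for validation against a forward model).
#'
#' @param mesh A [build_layer_mesh()] mesh.
#' @param material An [layer_model()] (overrides the mesh material if given).
#' @param sample_profile List with `r_mm` and `uz_mm` (sample-side axial
#'   displacement, positive = compression of the layer, i.e.
#'   `uz = L0 - thickness`), optional `ur_mm`, and optional
#'   `tangential` = `"friction"`, `"prescribed"` or `"free"`.
#' @param cfg An [compop_config()].
#' @return An `sop_fe_result` with nodal displacements, Gauss-point Cauchy
#'   stresses (kPa), convergence history and reactions.
#' @export
solve_layer_compression <- function(mesh, material = NULL, sample_profile,
                                    cfg = compop_config()) {
  stopifnot(inherits(mesh, "sop_fe_mesh"))
  if (!is.null(material)) {
    mesh$materials$layer <- material
  }
  material <- mesh$materials$layer
  tang <- sample_profile$tangential
  if (is.null(tang)) tang <- "friction"
  smp <- mesh$sets$sample
  r_s <- mesh$nodes[smp, 1]
  uz <- stats::approx(sample_profile$r_mm, sample_profile$uz_mm,
                      xout = r_s, rule = 2)$y
  bc <- data.frame(dof = 2L * smp, value = uz)
  # window: rigid plane, normal displacement zero
  win <- mesh$sets$window
  bc <- rbind(bc, data.frame(dof = 2L * win, value = 0))
  # axis of symmetry; in plane strain the lateral rigid-body mode has no
  # natural constraint (friction vanishes at zero pressure), so the lateral
  # gauge is pinned at the mid-width sample node
  if (mesh$mode == "axisymmetric") {
    ax <- mesh$sets$axis
    bc <- rbind(bc, data.frame(dof = 2L * ax - 1L, value = 0))
  } else if (tang != "prescribed") {
    mid <- smp[which.min(abs(r_s - stats::median(range(r_s))))]
    bc <- rbind(bc, data.frame(dof = 2L * mid - 1L, value = 0))
  }
  friction <- list()
  if (cfg$friction_coefficient > 0)
    friction <- c(friction, list(.friction_group(mesh, "window", material, cfg)))
  if (tang == "prescribed") {
    if (is.null(sample_profile$ur_mm))
      stop("invalid-argument: prescribed tangential motion needs ur_mm")
    ur <- stats::approx(sample_profile$r_mm, sample_profile$ur_mm,
                        xout = r_s, rule = 2)$y
    keep <- !(2L * smp - 1L) %in% bc$dof  # axis node already constrained
    bc <- rbind(bc, data.frame(dof = (2L * smp - 1L)[keep], value = ur[keep]))
  } else if (tang == "friction" && cfg$friction_coefficient > 0) {
    friction <- c(friction, list(.friction_group(mesh, "sample", material, cfg)))
  }
  bc <- bc[!duplicated(bc$dof), ]
  .fem_solve(mesh, cfg, bc, friction)
}

#' Interface true-stress profile from a converged solution
#'
#' Extrapolates the axial (surface-normal) Cauchy stress from the Gauss
#' points of the elements touching the requested boundary to the boundary
#' itself, reported per lateral position (deformed radius) under the
#' compressive-positive magnitude convention.
#'
#' @param result An `sop_fe_result`.
#' @param mesh The mesh it was computed on.
#' @param side `"sample"` (default) or `"window"`.
#' @return Data frame with `r_mm` (deformed), `R0_mm` (reference),
#'   `stress_kPa` (compressive-positive axial Cauchy stress), `s_rr_kPa`, and
#'   `eng_stress_kPa` (the same traction per reference area, i.e. Cauchy
#'   stress times the lateral area stretch `Frr * Ftheta`).
#' @export
interface_stress <- function(result, mesh, side = "sample") {
  stopifnot(inherits(result, "sop_fe_result"))
  gp <- result$gp_stress
  zb <- if (side == "sample") min(mesh$nodes[, 2]) else max(mesh$nodes[, 2])
  # elements with an edge on the boundary row
  zmin_e <- tapply(mesh$nodes[t(mesh$elems), 2],
                   rep(seq_len(nrow(mesh$elems)), each = 4),
                   if (side == "sample") min else max)
  on_b <- which(abs(zmin_e - zb) < 1e-9)
  rows <- gp[gp[, "elem"] %in% on_b, , drop = FALSE]
  out <- do.call(rbind, lapply(split(as.data.frame(rows), rows[, "elem"]),
    function(df) {
      # gauss points: 1 (-,-), 2 (+,-), 3 (+,+), 4 (-,+) in (xi, eta);
      # extrapolate along eta from +/- 1/sqrt(3) to the boundary
      lo <- if (side == "sample") c(1, 2) else c(4, 3)
      hi <- if (side == "sample") c(4, 3) else c(1, 2)
      a <- (1 + sqrt(3)) / 2
      b <- (1 - sqrt(3)) / 2
      szz <- a * df$s_zz[lo] + b * df$s_zz[hi]
      srr <- a * df$s_rr[lo] + b * df$s_rr[hi]
      area <- a * (df$Frr * df$Ftt)[lo] + b * (df$Frr * df$Ftt)[hi]
      rr <- a * df$r[lo] + b * df$r[hi]
      R0 <- a * df$R0[lo] + b * df$R0[hi]
      data.frame(r_mm = rr, R0_mm = R0, stress_kPa = -szz, s_rr_kPa = -srr,
                 eng_stress_kPa = -szz * area)
    }))
  out <- out[order(out$r_mm), ]
  rownames(out) <- NULL
  out
}
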