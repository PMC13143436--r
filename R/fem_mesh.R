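#' Solver configuration for computational optical palpation
#'
#' @param geometry_mode `"axisymmetric"` (exact for centered cylindrical
#'   scenes, the validation path) or `"plane_strain"` (row-wise approximation
#'   for arbitrary maps).
#' @param friction_coefficient Coulomb coefficient at the rigid contact
#'   surfaces; the default 0.2 corresponds to a lubricated layer.
#' @param element_size_mm Target element size at the sensing interface (mm).
#' @param newton_tolerance Relative residual tolerance of the Newton loop.
#' @param max_newton_iterations Iteration cap per load increment.
#' @param load_increments Number of equal displacement increments; increments
#'   are halved adaptively on divergence down to 1/16 of the base increment.
#' @param elastic_slip_mm Elastic-slip distance of the regularized Coulomb
#'   law (mm): the tangential traction is `-mu p tanh(u_t / elastic_slip_mm)`,
#'   reaching the Coulomb cap over about this much slip. A solver
#'   regularization knob, not physics; default 0.05 mm (1% of the layer
#'   thickness).
#' @param aspect_target_strain Compressive strain at which pre-stretched
#'   element aspect ratios should reach ~1:1 (elements are built taller by
#'   `1/(1 - strain)` so they become square after compression).
#' @return Object of class `sop_compop_config`.
#' @export
compop_config <- function(geometry_mode = c("axisymmetric", "plane_strain"),
                          friction_coefficient = 0.2,
                          element_size_mm = 0.2,
                          newton_tolerance = 1e-8,
                          max_newton_iterations = 60L,
                          load_increments = 20L,
                          elastic_slip_mm = 0.05,
                          aspect_target_strain = 0.4) {
  geometry_mode <- match.arg(geometry_mode)
  if (friction_coefficient < 0)
    stop("invalid-argument: friction_coefficient must be >= 0")
  if (element_size_mm <= 0)
    stop("invalid-argument: element_size_mm must be > 0")
  if (load_increments < 1L)
    stop("invalid-argument: load_increments must be >= 1")
  if (elastic_slip_mm <= 0)
    stop("invalid-argument: elastic_slip_mm must be > 0")
  if (aspect_target_strain < 0 || aspect_target_strain >= 1)
    stop("invalid-argument: aspect_target_strain must be in [0, 1)")
  structure(list(geometry_mode = geometry_mode,
                 friction_coefficient = friction_coefficient,
                 element_size_mm = element_size_mm,
                 newton_tolerance = newton_tolerance,
                 max_newton_iterations = as.integer(max_newton_iterations),
                 load_increments = as.integer(load_increments),
                 elastic_slip_mm = elastic_slip_mm,
                 aspect_target_strain = aspect_target_strain),
            class = "sop_compop_config")
}

# graded 1D breakpoints from a to b, spacing h0 at a growing geometrically
# to at most h1; h0 == h1 gives uniform spacing.
.mesh_line <- function(a, b, h0, h1 = h0, ratio = 1.2) {
  len <- b - a
  stopifnot(len > 0, h0 > 0)
  if (abs(h1 - h0) < 1e-12) {
    n <- max(1L, ceiling(len / h0 - 1e-9))
    return(seq(a, b, length.out = n + 1L))
  }
  h <- h0
  x <- a
  pts <- a
  while (x < b - 1e-9) {
    x <- x + h
    pts <- c(pts, x)
    h <- min(h * ratio, h1)
  }
  # rescale so the sequence ends exactly at b without a sliver interval
  pts <- a + (pts - a) * (len / (pts[length(pts)] - a))
  pts[length(pts)] <- b
  pts
}

# unique with tolerance (guards against ulp-level duplicate breakpoints when
# graded segments are concatenated)
.uniq_tol <- function(x, tol = 1e-8) {
  x <- sort(x)
  x[c(TRUE, diff(x) > tol)]
}

# tensor-product quad mesh from radial/axial breakpoints.
# Node numbering column-major in (r, z); element nodes counterclockwise.
.tensor_mesh <- function(r_breaks, z_breaks) {
  nr <- length(r_breaks)
  nz <- length(z_breaks)
  nodes <- cbind(rep(r_breaks, times = nz), rep(z_breaks, each = nr))
  idx <- function(i, j) (j - 1L) * nr + i   # i radial, j axial (1-based)
  e <- expand.grid(i = seq_len(nr - 1L), j = seq_len(nz - 1L))
  elems <- cbind(idx(e$i, e$j), idx(e$i + 1L, e$j),
                 idx(e$i + 1L, e$j + 1L), idx(e$i, e$j + 1L))
  list(nodes = nodes, elems = elems, nr = nr, nz = nz,
       r_breaks = r_breaks, z_breaks = z_breaks)
}

.mesh_object <- function(tm, mode, sets, material_id, materials) {
  jac_ok <- all(apply(tm$elems, 1, function(nd) {
    p <- tm$nodes[nd, ]
    (p[2, 1] - p[1, 1]) * (p[4, 2] - p[1, 2]) > 0
  }))
  if (!jac_ok) stop("invalid-argument: mesh has non-positive Jacobians")
  structure(list(nodes = tm$nodes, elems = tm$elems, mode = mode,
                 sets = sets, material_id = material_id,
                 materials = materials,
                 r_breaks = tm$r_breaks, z_breaks = tm$z_breaks),
            class = "sop_fe_mesh")
}

#' @export
print.sop_fe_mesh <- function(x, ...) {
  cat(sprintf("<sop_fe_mesh> %s, %d nodes, %d elements, %d material(s)\n",
              x$mode, nrow(x$nodes), nrow(x$elems), length(x$materials)))
  invisible(x)
}

#' Build a quadrilateral mesh of the compliant layer
#'
#' Structured mesh of the layer cross-section: radius (or half-width)
#' `lateral_extent_mm`, thickness `L0_mm`. Radial element size is
#' `cfg$element_size_mm`; axial sizes are pre-stretched by
#' `1/(1 - aspect_target_strain)` so elements approach unit aspect ratio
#' after the expected compression. Boundary node sets: `sample` (bottom,
#' z = 0, the sensing interface), `window` (top, z = L0), `axis` (r = 0) and
#' `lateral` (r = extent).
#'
#' @param layer An [layer_model()].
#' @param lateral_extent_mm Layer radius (axisymmetric) or half-width
#'   (plane strain); must cover the full layer (default 9.5 mm, the 19 mm
#'   layer disc).
#' @param cfg An [compop_config()].
#' @param coarsen_factor Growth of the radial and upper-axial element size
#'   away from the interface (1 = uniform mesh).
#' @param r_breaks Optional explicit radial node positions (mm, from 0 to
#'   the lateral extent), e.g. to align the sensing-interface nodes with an
#'   externally supplied displacement profile.
#' @return Object of class `sop_fe_mesh` with the layer material attached.
#' @export
build_layer_mesh <- function(layer, lateral_extent_mm = 9.5,
                             cfg = compop_config(), coarsen_factor = 2.5,
                             r_breaks = NULL) {
  h <- cfg$element_size_mm
  L0 <- layer$L0_mm
  if (h > L0 / 4)
    stop("invalid-argument: element size larger than layer thickness / 4")
  if (lateral_extent_mm <= 0)
    stop("invalid-argument: lateral extent must be > 0")
  hz <- h / (1 - cfg$aspect_target_strain)
  if (is.null(r_breaks))
    r_breaks <- .mesh_line(0, lateral_extent_mm, h, h * coarsen_factor)
  else r_breaks <- .uniq_tol(r_breaks)
  z_breaks <- .mesh_line(0, L0, hz, hz * coarsen_factor)
  tm <- .tensor_mesh(r_breaks, z_breaks)
  nr <- tm$nr; nz <- tm$nz
  sets <- list(sample = seq_len(nr),
               window = (nz - 1L) * nr + seq_len(nr),
               axis = (seq_len(nz) - 1L) * nr + 1L,
               lateral = (seq_len(nz) - 1L) * nr + nr)
  mat <- layer
  .mesh_object(tm, cfg$geometry_mode, sets,
               rep(1L, nrow(tm$elems)), list(layer = mat))
}

#' Build the two-material layer-on-phantom mesh
#'
#' Conforming structured mesh of the forward benchmark scene: the compliant
#' layer sitting on a soft phantom containing a stiff cylindrical inclusion,
#' compressed by the rigid imaging window from above. Radial and axial
#' breakpoints are aligned with the inclusion boundary and the layer-phantom
#' interface; elements are refined around the inclusion and the interface.
#' The domain is truncated at the layer radius (the inclusion sits many
#' layer thicknesses away from the lateral boundary).
#'
#' @param phantom A [phantom_spec()].
#' @param layer An [layer_model()].
#' @param cfg An [compop_config()].
#' @param fine_radius_mm Radius out to which the fine interface element size
#'   is kept before coarsening.
#' @param interface `"bonded"` (default): single shared nodes. `"friction"`:
#'   lubricated frictional contact — interface nodes are duplicated, tied
#'   normally by a stiff penalty and coupled tangentially by the regularized
#'   Coulomb law; note this bilateral tie cannot represent separation.
#' @return An `sop_fe_mesh` with materials `layer`, `background`,
#'   `inclusion` and node sets `base`, `interface` (layer side; plus
#'   `interface_phantom` and `interface_pairs` for the frictional variant)
#'   in addition to the layer sets.
#' @export
build_phantom_mesh <- function(phantom, layer, cfg = compop_config(),
                               fine_radius_mm = 2.5,
                               interface = c("bonded", "friction")) {
  interface <- match.arg(interface)
  h <- cfg$element_size_mm
  hf <- min(h, phantom$inclusion_diameter_mm / 6)
  L0 <- layer$L0_mm
  Hp <- phantom$phantom_thickness_mm
  r_inc <- phantom$inclusion_diameter_mm / 2
  z_top_inc <- Hp - phantom$inclusion_depth_below_surface_mm
  z_bot_inc <- z_top_inc - phantom$inclusion_thickness_mm
  if (z_bot_inc < 0 || r_inc >= phantom$phantom_diameter_mm / 2)
    stop("invalid-argument: inclusion does not fit inside the phantom")
  extent <- min(phantom$phantom_diameter_mm / 2, 9.5)
  r_breaks <- .uniq_tol(c(.mesh_line(0, r_inc, hf),
                          .mesh_line(r_inc, min(fine_radius_mm, extent), hf, h),
                          .mesh_line(min(fine_radius_mm, extent), extent,
                                     h, 3 * h)))
  hz_layer <- h / (1 - cfg$aspect_target_strain)
  cap <- max(phantom$inclusion_depth_below_surface_mm, 1e-6)
  z_breaks <- .uniq_tol(c(
    .mesh_line(0, max(z_bot_inc, 0.2), min(2 * h, max(z_bot_inc, 0.2))),
    .mesh_line(max(z_bot_inc, 0.2), z_top_inc, h),
    .mesh_line(z_top_inc, Hp, min(hf, cap / 2)),
    .mesh_line(Hp, Hp + L0, min(hf * 1.5, hz_layer), 2 * hz_layer)))
  tm <- .tensor_mesh(r_breaks, z_breaks)
  nr <- tm$nr; nz <- tm$nz
  j_int <- which.min(abs(tm$z_breaks - Hp))
  sets <- list(base = seq_len(nr),
               window = (nz - 1L) * nr + seq_len(nr),
               axis = (seq_len(nz) - 1L) * nr + 1L,
               lateral = (seq_len(nz) - 1L) * nr + nr,
               interface = (j_int - 1L) * nr + seq_len(nr))
  cen_r <- rowMeans(matrix(tm$nodes[tm$elems, 1], ncol = 4))
  cen_z <- rowMeans(matrix(tm$nodes[tm$elems, 2], ncol = 4))
  mat_id <- ifelse(cen_z > Hp, 1L,
                   ifelse(cen_r < r_inc & cen_z > z_bot_inc & cen_z < z_top_inc,
                          3L, 2L))
  materials <- list(
    layer = layer,
    background = layer_model(L0_mm = Hp,
                             C10_kPa = phantom$background_modulus_kPa / 6,
                             poisson_ratio = layer$poisson_ratio),
    inclusion = layer_model(L0_mm = phantom$inclusion_thickness_mm,
                            C10_kPa = phantom$inclusion_modulus_kPa / 6,
                            poisson_ratio = layer$poisson_ratio))
  mesh <- .mesh_object(tm, cfg$geometry_mode, sets, mat_id, materials)
  if (interface == "friction") mesh <- .split_interface(mesh, cen_z, Hp)
  mesh
}

# duplicate the interface-row nodes: originals stay with the layer-side
# elements, duplicates take over the phantom-side elements; the pairs are
# later tied normally (penalty) and coupled by tangential friction
.split_interface <- function(mesh, cen_z, Hp) {
  orig <- mesh$sets$interface
  n0 <- nrow(mesh$nodes)
  dup <- n0 + seq_along(orig)
  mesh$nodes <- rbind(mesh$nodes, mesh$nodes[orig, , drop = FALSE])
  below <- which(cen_z < Hp)
  remap <- integer(n0)
  remap[orig] <- dup
  for (e in below) {
    nd <- mesh$elems[e, ]
    hit <- nd %in% orig
    if (any(hit)) mesh$elems[e, hit] <- remap[nd[hit]]
  }
  mesh$sets$interface_phantom <- dup
  mesh$sets$interface_pairs <- cbind(layer = orig, phantom = dup)
  # duplicated node on the symmetry axis needs the radial constraint too
  r0 <- which(mesh$nodes[dup, 1] == 0)
  if (length(r0)) mesh$sets$axis <- c(mesh$sets$axis, dup[r0])
  mesh
}

#' Export a mesh (and optional nodal field) as legacy ASCII VTK
#'
#' Minimal unstructured-grid writer for inspection in standard mesh viewers.
#'
#' @param mesh An `sop_fe_mesh`.
#' @param path Output `.vtk` path.
#' @param point_data Optional named list of per-node numeric vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "sopal mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)),
             con)
  utils::write.table(cbind(mesh$nodes, 0), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  utils::write.table(cbind(4L, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(9L, m)), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nm]], digits = 9), con)
    }
  }
  invisible(path)
}
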