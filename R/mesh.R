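# Cartesian-core volume meshing of the airway lumen.  Cells of a uniform
# lattice are classified against the implicit model carried by the surface:
# fluid (lumen interior), boundary-ghost layers beyond each inlet/outlet cap
# (used to apply velocity-inlet / pressure-outlet conditions), or solid.
# A conforming tetrahedral decomposition (6 tets per fluid cell) is available
# for export and reporting; near-wall fidelity comes from sub-cell wall
# distances sampled from the signed-distance field rather than from extruded
# prism layers.

.GHOST_LAYERS <- 3 # ghost-layer depth beyond each cap, in cells

#' Volume mesh of an airway surface
#'
#' @param surface An [build_surface()] result (must carry its generating
#'   centerline model, which supplies the exact signed-distance field used
#'   for cell classification and near-wall distances).
#' @param target_cell_size Lattice spacing in metres.
#' @param n_layers Number of near-wall strata (wall-distance bands of one
#'   cell width) to tag; the tags drive near-wall post-processing.
#' @return An object of class `volume_mesh`: lattice dims, `origin` (centre
#'   of the first cell), `h`, `celltype` (-1 solid, 0 fluid, k >= 1 ghost of
#'   cap patch k in `patches`), `nearest_segment`, `phi` (signed distance),
#'   `layer`, `patches` (cap patch table with discrete vector areas),
#'   cell/tet counts and quality metrics.
#' @export
generate_volume_mesh <- function(surface, target_cell_size, n_layers = 0L) {
  stopifnot(inherits(surface, "airway_surface"), target_cell_size > 0,
            n_layers >= 0)
  tree <- surface$tree
  if (is.null(tree))
    stop("surface does not carry its generating centerline model")
  h <- target_cell_size
  ext <- .GHOST_LAYERS * h
  pairs <- .smooth_pairs(tree)
  kmax <- if (length(pairs)) max(vapply(pairs, `[`, 0, 3)) else 0
  bb <- .tree_bbox(tree, margin = ext + 2 * h + kmax / 2)
  # symmetric lattice about the y = 0 and z = 0 planes so that the mirror
  # symmetry of the geometry is discrete, not just approximate
  ymax <- max(abs(bb[, 2])); zmax <- max(abs(bb[, 3]))
  nx <- ceiling((bb[2, 1] - bb[1, 1]) / h)
  ny <- 2L * ceiling(ymax / h)
  nz <- 2L * ceiling(zmax / h)
  origin <- c(bb[1, 1] + h / 2, -(ny / 2 - 0.5) * h, -(nz / 2 - 0.5) * h)
  dims <- c(nx, ny, nz)
  centers <- cbind(
    origin[1] + (rep(seq_len(nx), times = ny * nz) - 1) * h,
    origin[2] + (rep(rep(seq_len(ny), each = nx), times = nz) - 1) * h,
    origin[3] + (rep(seq_len(nz), each = nx * ny) - 1) * h)
  cls <- .airway_phi(centers, tree, extend = ext)
  celltype <- rep(-1L, nrow(centers))
  celltype[cls$phi < 0] <- 0L
  ghost <- cls$phi >= 0 & cls$cap > 0L & cls$cap_depth <= ext
  celltype[ghost] <- cls$cap[ghost]
  nfluid <- sum(celltype == 0L)
  if (nfluid == 0L)
    stop("no fluid cells: target_cell_size too coarse for this geometry")
  layer <- integer(nrow(centers))
  if (n_layers > 0) {
    fl <- celltype == 0L
    layer[fl] <- pmin(ceiling(-cls$phi[fl] / h), n_layers)
  }

  # discrete cap areas: vector sum of lattice faces between fluid and each
  # ghost patch (the magnitude equals the projected open area of the cap)
  arr <- array(celltype, dims)
  patches <- tree$caps
  va <- matrix(0, nrow(patches), 3)
  for (ax in 1:3) {
    idx0 <- lapply(dims, seq_len); idx1 <- idx0
    idx0[[ax]] <- seq_len(dims[ax] - 1L); idx1[[ax]] <- 2:dims[ax]
    t0 <- do.call(`[`, c(list(arr), idx0)); t1 <- do.call(`[`, c(list(arr), idx1))
    for (pk in seq_len(nrow(patches))) {
      va[pk, ax] <- (sum(t0 == 0L & t1 == pk) - sum(t1 == 0L & t0 == pk)) * h^2
    }
  }
  patches$area_x <- va[, 1]; patches$area_y <- va[, 2]; patches$area_z <- va[, 3]
  patches$open_area <- sqrt(rowSums(va^2))

  structure(list(
    dims = dims, origin = origin, h = h, celltype = celltype,
    nearest_segment = cls$nearest, phi = cls$phi, layer = layer,
    n_layers = as.integer(n_layers),
    patches = patches, tree = tree, surface_spacing = surface$spacing,
    n_fluid_cells = nfluid, n_cells = 6L * nfluid,
    volume = nfluid * h^3,
    # Kuhn tetrahedra are identical up to reflection: fixed quality metrics
    quality = list(min_dihedral_deg = 35.26, max_aspect_ratio = sqrt(3)),
    ghost_extent = ext
  ), class = "volume_mesh")
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf(
    "Volume mesh '%s': %d x %d x %d lattice, h = %.3g mm\n",
    x$tree$name, x$dims[1], x$dims[2], x$dims[3], x$h * 1e3))
  cat(sprintf("%d fluid cells (%d tetrahedra), volume %.4g mm^3\n",
              x$n_fluid_cells, x$n_cells, x$volume * 1e9))
  invisible(x)
}

# Sub-cell wall distances at lattice face centres that border a wall,
# passed to the solver's near-wall diffusion correction.  For each face
# axis the distance to the wall is resolved along the two transverse lattice
# axes (gap = |phi| / |n_axis|): the conductance of a no-slip wall seen
# through an oblique stairstep boundary depends on the axis-aligned gap.
.face_wall_distances <- function(mesh) {
  dims <- mesh$dims; h <- mesh$h; origin <- mesh$origin
  arr <- array(mesh$celltype, dims)
  solid <- arr < 0L
  out <- vector("list", 6)
  m <- 0L
  for (ax in 1:3) {
    taxes <- c((ax %% 3) + 1L, ((ax + 1L) %% 3) + 1L) # t1, t2 as in the core
    fd <- dims; fd[ax] <- fd[ax] + 1L
    # a face needs wall distances if an adjacent cell is fluid and a
    # transverse neighbour cell is solid
    near_solid <- array(FALSE, dims)
    for (tax in taxes) {
      shp <- function(d) {
        i <- lapply(dims, seq_len)
        i[[tax]] <- pmin(pmax(seq_len(dims[tax]) + d, 1L), dims[tax])
        i
      }
      near_solid <- near_solid |
        do.call(`[`, c(list(solid), shp(+1L))) |
        do.call(`[`, c(list(solid), shp(-1L)))
    }
    fluidish <- arr == 0L & near_solid
    fmask <- array(FALSE, fd)
    idxlo <- lapply(fd, seq_len); idxlo[[ax]] <- seq_len(dims[ax])
    idxhi <- lapply(fd, seq_len); idxhi[[ax]] <- seq_len(dims[ax]) + 1L
    fmask <- do.call(`[<-`, c(list(fmask), idxlo,
                              list(do.call(`[`, c(list(fmask), idxlo)) | fluidish)))
    fmask <- do.call(`[<-`, c(list(fmask), idxhi,
                              list(do.call(`[`, c(list(fmask), idxhi)) | fluidish)))
    w <- which(fmask)
    d1 <- rep(-1, prod(fd)); d2 <- rep(-1, prod(fd))
    if (length(w)) {
      ijk <- arrayInd(w, fd)
      pts <- cbind(origin[1] + (ijk[, 1] - 1) * h - (ax == 1) * h / 2,
                   origin[2] + (ijk[, 2] - 1) * h - (ax == 2) * h / 2,
                   origin[3] + (ijk[, 3] - 1) * h - (ax == 3) * h / 2)
      phi <- .wall_phi(pts, mesh$tree, extend = mesh$ghost_extent)
      nrm <- .wall_normal(pts, mesh$tree, eps = h / 4)
      gap <- function(tax) pmax(-phi, 0.01 * h) / pmax(abs(nrm[, tax]), 0.15)
      d1[w] <- gap(taxes[1]); d2[w] <- gap(taxes[2])
    }
    out[[m + 1L]] <- d1; out[[m + 2L]] <- d2
    m <- m + 2L
  }
  names(out) <- c("u1", "u2", "v1", "v2", "w1", "w2")
  out
}

#' Grid convergence index
#'
#' Richardson-extrapolation-based relative discretization-error estimate for
#' a pair of solutions on systematically refined grids, with safety factor
#' 1.25 (three-grid studies).
#'
#' @param f_coarse,f_fine Scalar solution metric on the coarse/fine grid.
#' @param refinement_ratio Linear refinement ratio (> 1).
#' @param order Observed (or assumed) order of accuracy (> 0).
#' @param safety_factor Multiplicative safety factor (default 1.25).
#' @return GCI as a fraction.
#' @examples
#' grid_convergence_index(1.01, 1.00, 2, 2) # 1.25 * 0.01 / 3
#' @export
grid_convergence_index <- function(f_coarse, f_fine, refinement_ratio, order,
                                   safety_factor = 1.25) {
  stopifnot(refinement_ratio > 1, order > 0)
  if (f_fine == 0) stop("fine-grid metric is zero; GCI undefined")
  safety_factor * abs((f_coarse - f_fine) / f_fine) /
    (refinement_ratio^order - 1)
}

#' Mesh-independence study
#'
#' Solves the same flow problem on a ladder of successively finer meshes,
#' records a probe metric (the average velocity magnitude at the probe path
#' points), and selects the coarsest level whose relative change to the next
#' finer level is below `tolerance`.  If no level qualifies the finest level
#' is selected and flagged.
#'
#' @param surface An [build_surface()] result.
#' @param size_ladder Decreasing vector of target cell sizes (m), length >= 2.
#' @param solve_fn Function of one argument (the [generate_volume_mesh()]
#'   result) returning either a [solve_steady()] solution or a numeric
#'   scalar metric directly.
#' @param probe_set A [make_probe_set()] result (used when `solve_fn`
#'   returns a solution).
#' @param tolerance Relative-change tolerance (fraction, default 0.003).
#' @return An object of class `mesh_study`: data frame `levels` (cell size,
#'   cell count, metric, relative change, GCI), `selected` (index),
#'   `tolerance_met` (flag).
#' @export
mesh_independence_study <- function(surface, size_ladder, solve_fn, probe_set,
                                    tolerance = 0.003) {
  stopifnot(length(size_ladder) >= 2, all(diff(size_ladder) < 0),
            tolerance > 0, tolerance < 1)
  metrics <- numeric(length(size_ladder))
  cells <- integer(length(size_ladder))
  for (l in seq_along(size_ladder)) {
    mesh <- generate_volume_mesh(surface, size_ladder[l])
    cells[l] <- mesh$n_cells
    r <- solve_fn(mesh)
    metrics[l] <- if (is.numeric(r)) r else probe_average_velocity(r, probe_set)
  }
  relchg <- c(NA, abs(diff(metrics)) / abs(metrics[-1]))
  # change of level l = relative change to the next finer level
  chg_next <- c(relchg[-1], NA)
  gci <- c(NA, vapply(seq_along(metrics)[-1], function(l) {
    grid_convergence_index(metrics[l - 1], metrics[l],
                           size_ladder[l - 1] / size_ladder[l], order = 2)
  }, 0))
  ok <- which(!is.na(chg_next) & chg_next < tolerance)
  tolerance_met <- length(ok) > 0
  selected <- if (tolerance_met) min(ok) else length(metrics)
  if (!tolerance_met)
    warning("no ladder level met the mesh-convergence tolerance; ",
            "finest level selected")
  structure(list(
    levels = data.frame(cell_size = size_ladder, cell_count = cells,
                        metric = metrics, rel_change_to_finer = chg_next,
                        gci = gci),
    selected = selected, tolerance = tolerance, tolerance_met = tolerance_met
  ), class = "mesh_study")
}

#' @export
print.mesh_study <- function(x, ...) {
  cat(sprintf("Mesh-independence study (tolerance %.2g%%):\n",
              100 * x$tolerance))
  print(transform(x$levels, cell_size = cell_size * 1e3), row.names = FALSE)
  cat(sprintf("Selected level %d (%s)\n", x$selected,
              if (x$tolerance_met) "tolerance met" else "tolerance NOT met"))
  invisible(x)
}

#' Tetrahedral decomposition of the fluid cells
#'
#' Splits every fluid lattice cell into 6 tetrahedra (Kuhn subdivision).
#' Used for mesh export; the solver operates on the lattice itself.
#'
#' @param mesh A [generate_volume_mesh()] result.
#' @return List with `vertices` (n x 3) and `tetrahedra` (m x 4, 1-based).
#' @export
mesh_tetrahedra <- function(mesh) {
  dims <- mesh$dims; h <- mesh$h; origin <- mesh$origin
  fl <- which(mesh$celltype == 0L)
  ijk <- arrayInd(fl, dims)
  # node lattice of cell corners, indexed globally
  nd <- dims + 1L
  nid <- function(i, j, k) i + (nd[1]) * ((j - 1L) + nd[2] * (k - 1L)) # i in 1..nd1
  corners <- list(c(0,0,0), c(1,0,0), c(0,1,0), c(1,1,0),
                  c(0,0,1), c(1,0,1), c(0,1,1), c(1,1,1))
  cix <- sapply(corners, function(o) nid(ijk[,1] + o[1], ijk[,2] + o[2], ijk[,3] + o[3]))
  kuhn <- list(c(1,2,4,8), c(1,4,3,8), c(1,3,7,8), c(1,7,5,8), c(1,5,6,8), c(1,6,2,8))
  tets <- do.call(rbind, lapply(kuhn, function(tt) cix[, tt, drop = FALSE]))
  used <- sort(unique(as.vector(tets)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], nrow(tets), 4)
  u0 <- used - 1L
  iu <- u0 %% nd[1]; ju <- (u0 %/% nd[1]) %% nd[2]; ku <- u0 %/% (nd[1] * nd[2])
  verts <- cbind(origin[1] + (iu - 0.5) * h,
                 origin[2] + (ju - 0.5) * h,
                 origin[3] + (ku - 0.5) * h)
  list(vertices = verts, tetrahedra = tets)
}
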