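# Boundary-condition configuration and the steady laminar flow solve.

#' Solver settings
#'
#' Defaults follow standard segregated-SIMPLE practice for laminar internal
#' flows: under-relaxation 0.3 (pressure) / 0.5 (momentum), scaled-residual
#' convergence below 1e-5 for all equations, second-order-upwind momentum
#' with second-order (central) pressure.
#'
#' @param underrelax_pressure,underrelax_momentum Under-relaxation factors
#'   in (0, 1].
#' @param residual_tolerance Scaled-residual convergence criterion
#'   (normalized by the first-iteration residual of each equation).
#' @param max_outer_iterations Outer SIMPLE iteration cap.
#' @param n_sweeps Gauss-Seidel sweeps per momentum equation per outer
#'   iteration.
#' @param cg_max,cg_tol Conjugate-gradient cap and relative tolerance for the
#'   pressure-correction solve.
#' @param second_order Use the explicit second-order-upwind deferred
#'   correction for momentum advection.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(underrelax_pressure = 0.3,
                            underrelax_momentum = 0.5,
                            residual_tolerance = 1e-5,
                            max_outer_iterations = 4000L,
                            n_sweeps = 3L, cg_max = 40L, cg_tol = 1e-2,
                            second_order = TRUE) {
  stopifnot(underrelax_pressure > 0, underrelax_pressure <= 1,
            underrelax_momentum > 0, underrelax_momentum <= 1,
            residual_tolerance > 0)
  structure(list(underrelax_pressure = underrelax_pressure,
                 underrelax_momentum = underrelax_momentum,
                 residual_tolerance = residual_tolerance,
                 max_outer_iterations = as.integer(max_outer_iterations),
                 n_sweeps = as.integer(n_sweeps), cg_max = as.integer(cg_max),
                 cg_tol = cg_tol, second_order = second_order),
            class = "solver_settings")
}

#' Boundary conditions for a breathing phase
#'
#' Inspiration: uniform velocity inlet on the root (G6) cap carrying the
#' phase flow divided by `2^g` for root generation `g` (symmetric Weibel
#' split), all tip caps as 0 Pa pressure outlets.  Expiration: each tip cap
#' becomes a uniform velocity inlet carrying the expiratory branch flow of
#' its generation, the root cap a 0 Pa pressure outlet.  Walls are no-slip.
#'
#' @param mesh A [generate_volume_mesh()] result.
#' @param pattern A [breathing_pattern()].
#' @param phase `"inspiration"` or `"expiration"`.
#' @return An object of class `bc_set`: data frame with one row per cap
#'   patch (`patch`, `role`, `Q` m^3/s into the domain, direction, mean
#'   speed) plus the phase.
#' @export
configure_phase <- function(mesh, pattern, phase = c("inspiration", "expiration")) {
  phase <- match.arg(phase)
  stopifnot(inherits(mesh, "volume_mesh"), inherits(pattern, "breathing_pattern"))
  Qp <- phase_flow_rates(pattern)[[phase]]
  caps <- mesh$patches
  segs <- mesh$tree$segments
  gen <- segs$generation[match(caps$segment, segs$id)]
  bc <- data.frame(patch = caps$patch, stringsAsFactors = FALSE)
  if (phase == "inspiration") {
    bc$role <- ifelse(caps$patch == "inlet", "velocity", "pressure")
  } else {
    bc$role <- ifelse(caps$patch == "inlet", "pressure", "velocity")
  }
  bc$Q <- ifelse(bc$role == "velocity",
                 vapply(gen, function(g) branch_flow_rate(Qp, g), 0), 0)
  # cap normals point outward; inflow enters along -normal
  bc$dx <- -caps$nx; bc$dy <- -caps$ny; bc$dz <- -caps$nz
  bc$speed <- ifelse(bc$role == "velocity",
                     mean_inlet_velocity(bc$Q, 2 * caps$radius), 0)
  structure(list(table = bc, phase = phase, pattern = pattern),
            class = "bc_set")
}

# Manual boundary conditions for fixture cases: flow Q (m^3/s) pushed into
# the named patch, all other caps as 0 Pa outlets.
.bc_flow_at <- function(mesh, inlet_patch, Q) {
  caps <- mesh$patches
  bc <- data.frame(patch = caps$patch, stringsAsFactors = FALSE)
  bc$role <- ifelse(caps$patch == inlet_patch, "velocity", "pressure")
  bc$Q <- ifelse(bc$role == "velocity", Q, 0)
  bc$dx <- -caps$nx; bc$dy <- -caps$ny; bc$dz <- -caps$nz
  bc$speed <- ifelse(bc$role == "velocity",
                     mean_inlet_velocity(Q, 2 * caps$radius), 0)
  structure(list(table = bc, phase = "fixture", pattern = NULL),
            class = "bc_set")
}

#' Steady laminar incompressible flow solve
#'
#' Solves the steady incompressible Navier-Stokes equations (continuity
#' `div v = 0` and momentum `rho v . grad v = -grad p + mu lap v`) on the
#' lattice mesh with the SIMPLE segregated algorithm: implicit upwind +
#' deferred second-order-upwind momentum, central pressure, under-relaxed
#' pressure correction, no-slip walls with sub-cell wall distances.
#' Initialization is quiescent (zero velocity, zero gauge pressure);
#' iteration ordering is fixed, so results are bit-deterministic for a given
#' mesh, boundary conditions and settings.
#'
#' @param mesh A [generate_volume_mesh()] result.
#' @param bcs A [configure_phase()] (or fixture) boundary-condition set.
#' @param fluid A [fluid_properties()].
#' @param settings A [solver_settings()].
#' @return An object of class `flow_solution`: cell-centred velocity
#'   components `uc`,`vc`,`wc` and magnitude `speed` (m/s), gauge pressure
#'   `p` (Pa), raw staggered face velocities, `converged`, `iterations`,
#'   `residuals` history, per-patch volume fluxes (m^3/s, positive into the
#'   domain) and the relative global mass imbalance.  Never throws on
#'   non-convergence; inspect `converged`.
#' @export
solve_steady <- function(mesh, bcs, fluid = fluid_properties(),
                         settings = solver_settings()) {
  stopifnot(inherits(mesh, "volume_mesh"), inherits(bcs, "bc_set"),
            inherits(fluid, "fluid_properties"),
            inherits(settings, "solver_settings"))
  bc <- bcs$table
  caps <- mesh$patches
  stopifnot(identical(bc$patch, caps$patch))
  role <- ifelse(bc$role == "velocity", 0L, 1L)
  dir <- as.matrix(bc[, c("dx", "dy", "dz")])
  # laminar-regime guard
  for (m in which(role == 0L)) {
    Re <- reynolds_number(abs(bc$speed[m]), 2 * caps$radius[m], fluid)
    if (is.finite(Re) && Re > 2000)
      warning(sprintf("patch %s: Reynolds number %.0f exceeds 2000; %s",
                      bc$patch[m], Re,
                      "the laminar model is questionable here"))
  }
  wd <- .face_wall_distances(mesh)
  res <- .cpp_simple_solve(
    as.integer(mesh$dims), mesh$h, as.integer(mesh$celltype),
    role, dir, bc$Q, wd,
    fluid$density, fluid$dynamic_viscosity,
    settings$underrelax_momentum, settings$underrelax_pressure,
    settings$residual_tolerance, settings$max_outer_iterations,
    settings$n_sweeps, settings$cg_max, settings$cg_tol,
    settings$second_order)
  dims <- mesh$dims
  fu <- array(res$u, dims + c(1, 0, 0))
  fv <- array(res$v, dims + c(0, 1, 0))
  fw <- array(res$w, dims + c(0, 0, 1))
  uc <- 0.5 * (fu[-(dims[1] + 1), , , drop = FALSE] + fu[-1, , , drop = FALSE])
  vc <- 0.5 * (fv[, -(dims[2] + 1), , drop = FALSE] + fv[, -1, , drop = FALSE])
  wc <- 0.5 * (fw[, , -(dims[3] + 1), drop = FALSE] + fw[, , -1, drop = FALSE])
  influx <- sum(pmax(res$patch_flux, 0))
  imbalance <- if (influx > 0) abs(sum(res$patch_flux)) / influx else 0
  colnames(res$residuals) <- c("u", "v", "w", "continuity")
  structure(list(
    mesh = mesh, bcs = bcs, fluid = fluid, settings = settings,
    uc = uc, vc = vc, wc = wc,
    speed = sqrt(uc^2 + vc^2 + wc^2),
    p = array(res$p, dims),
    face_u = fu, face_v = fv, face_w = fw,
    converged = res$converged, iterations = res$iterations,
    residuals = res$residuals,
    patch_flux = setNames(as.numeric(res$patch_flux), bc$patch),
    mass_imbalance = imbalance
  ), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf(
    "Steady laminar flow solution on '%s' (%s): %s after %d iterations\n",
    x$mesh$tree$name, x$bcs$phase,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  cat(sprintf(
    "max |v| = %.4g m/s, global mass imbalance %.3g%%\n",
    max(x$speed[array(x$mesh$celltype == 0L, x$mesh$dims)]),
    100 * x$mass_imbalance))
  invisible(x)
}

#' Poiseuille resistance-network pressure drop
#'
#' Analytic lower-bound oracle for the tree pressure drop: fully developed
#' laminar (Hagen-Poiseuille) resistance per segment,
#' `dP = 128 mu L Q / (pi D^4)`, with the branch flow halving at every
#' bifurcation; the root-to-tip total follows one (any, by symmetry)
#' root-to-tip path.  Entrance and bifurcation losses are not modelled, so a
#' resolved flow solve must produce at least this drop.
#'
#' @param tree A [build_centerline_tree()] result.
#' @param Q_root Volumetric flow into the tree root, m^3/s.
#' @param fluid A [fluid_properties()].
#' @return An object of class `network_drop`: per-segment drops (Pa) and the
#'   root-to-tip total.
#' @export
poiseuille_network_drop <- function(tree, Q_root, fluid = fluid_properties()) {
  stopifnot(inherits(tree, "centerline_tree"), Q_root >= 0)
  s <- tree$segments
  if (any(s$radius <= 0)) stop("zero segment diameter")
  depth <- s$generation - s$generation[1]
  Q_seg <- Q_root / 2^depth
  drop <- 128 * fluid$dynamic_viscosity * s$L * Q_seg / (pi * (2 * s$radius)^4)
  per_seg <- data.frame(segment = s$id, generation = s$generation,
                        Q = Q_seg, drop = drop)
  total <- 0; id <- s$id[s$parent == 0L][1]
  while (length(id) == 1L && !is.na(id)) {
    total <- total + drop[s$id == id]
    id <- s$id[s$parent == id & s$side == "right"][1]
  }
  structure(list(per_segment = per_seg, total = total), class = "network_drop")
}

#' @export
print.network_drop <- function(x, ...) {
  cat("Poiseuille network drop (Pa):\n")
  print(x$per_segment, row.names = FALSE)
  cat(sprintf("root-to-tip total: %.4g Pa\n", x$total))
  invisible(x)
}
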