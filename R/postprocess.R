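# Post-processing of flow solutions: probe and section statistics, maxima,
# pressure drop, wall shear stress, streamlines, and the cross-case report.

# Masked trilinear interpolation of a cell-centred lattice field.
.interp_field <- function(solution, field, pts, fluid_only = TRUE) {
  mesh <- solution$mesh
  .cpp_interp_cells(as.integer(mesh$dims), mesh$origin, mesh$h,
                    as.numeric(field), as.integer(mesh$celltype),
                    pts, fluid_only)
}

# Interpolated velocity vectors at points (n x 3 matrix).
.interp_velocity <- function(solution, pts) {
  cbind(u = .interp_field(solution, solution$uc, pts),
        v = .interp_field(solution, solution$vc, pts),
        w = .interp_field(solution, solution$wc, pts))
}

#' Probe-line average velocity
#'
#' Arithmetic mean of the velocity magnitude interpolated at the probe path
#' points (the mesh-independence metric: five points on the axis of the
#' right branch one generation below the root).
#'
#' @param solution A [solve_steady()] result.
#' @param probe_set A [make_probe_set()] result.
#' @return Mean speed in m/s.
#' @export
probe_average_velocity <- function(solution, probe_set) {
  stopifnot(inherits(solution, "flow_solution"), inherits(probe_set, "probe_set"))
  v <- .interp_velocity(solution, probe_set$path_points)
  if (anyNA(v)) stop("probe point outside the fluid region")
  mean(sqrt(rowSums(v^2)))
}

# Area quadrature on a disk: tensor product of Gauss-Legendre nodes in the
# squared-radius coordinate (uniform in area) and a uniform angular grid.
.disk_quadrature <- function(center, normal, radius, n_r = 8L, n_theta = 16L) {
  gl <- list( # 8-point Gauss-Legendre on [0, 1]
    x = c(0.01985507, 0.10166676, 0.23723379, 0.40828268, 0.59171732,
          0.76276621, 0.89833324, 0.98014493),
    w = c(0.05061427, 0.11119052, 0.15685332, 0.18134189, 0.18134189,
          0.15685332, 0.11119052, 0.05061427))
  stopifnot(n_r == 8L)
  nrm <- normal / sqrt(sum(normal^2))
  ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  th <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  r <- radius * sqrt(gl$x)
  pts <- matrix(0, n_r * n_theta, 3)
  wts <- numeric(n_r * n_theta)
  m <- 1L
  for (ir in seq_len(n_r)) {
    for (it in seq_len(n_theta)) {
      pts[m, ] <- center + r[ir] * (cos(th[it]) * e1 + sin(th[it]) * e2)
      wts[m] <- gl$w[ir] / n_theta # fraction of the disk area
      m <- m + 1L
    }
  }
  list(points = pts, weights = wts, area = pi * radius^2, normal = nrm)
}

#' Cross-section velocity statistics
#'
#' Area-weighted average and centre-point velocity magnitude, and the volume
#' flux, over each mid-segment cross-section of the probe set.  Quadrature
#' points that fall outside the fluid (possible near the wall at coarse
#' resolution) contribute zero velocity, consistent with no-slip.
#'
#' @param solution A [solve_steady()] result.
#' @param probe_set A [make_probe_set()] result.
#' @return Data frame: segment, generation, area (m^2), `avg_speed`,
#'   `center_speed` (m/s), `flux` (m^3/s, signed along the segment
#'   direction).
#' @export
section_stats <- function(solution, probe_set) {
  stopifnot(inherits(solution, "flow_solution"), inherits(probe_set, "probe_set"))
  ms <- probe_set$mid_sections
  out <- ms[, c("segment", "generation")]
  out$area <- out$avg_speed <- out$center_speed <- out$flux <- NA_real_
  h <- solution$mesh$h
  for (r in seq_len(nrow(ms))) {
    # integrate slightly past the nominal radius so the full discrete lumen
    # (the stairstep boundary straddles the circle) is captured; the
    # unmasked interpolation tapers to the zero field held in solid cells,
    # consistent with the staggered no-slip discretization
    rq <- ms$radius[r] + 0.45 * h
    qd <- .disk_quadrature(c(ms$cx[r], ms$cy[r], ms$cz[r]),
                           c(ms$nx[r], ms$ny[r], ms$nz[r]), rq,
                           n_theta = 32L)
    v <- cbind(.interp_field(solution, solution$uc, qd$points, FALSE),
               .interp_field(solution, solution$vc, qd$points, FALSE),
               .interp_field(solution, solution$wc, qd$points, FALSE))
    v[is.na(v)] <- 0
    spd <- sqrt(rowSums(v^2))
    vn <- v %*% qd$normal
    area_nominal <- pi * ms$radius[r]^2
    out$area[r] <- area_nominal
    out$avg_speed[r] <- sum(qd$weights * spd) * qd$area / area_nominal
    out$flux[r] <- sum(qd$weights * vn) * qd$area
    cv <- .interp_velocity(solution,
                           matrix(c(ms$cx[r], ms$cy[r], ms$cz[r]), 1, 3))
    out$center_speed[r] <- sqrt(sum(cv^2))
  }
  out
}

#' Maximum velocity magnitude
#'
#' Maximum over fluid lattice cells, with the generation of the airway
#' segment nearest the location, plus the 0.999 quantile as a guard against
#' isolated single-cell maxima.
#'
#' @param solution A [solve_steady()] result.
#' @return List: `max` (m/s), `location` (xyz, m), `generation`,
#'   `q999` (m/s).
#' @export
max_velocity <- function(solution) {
  stopifnot(inherits(solution, "flow_solution"))
  mesh <- solution$mesh
  fl <- mesh$celltype == 0L
  spd <- as.numeric(solution$speed)[fl]
  idx <- which(fl)[which.max(spd)]
  ijk <- arrayInd(idx, mesh$dims)
  loc <- mesh$origin + (ijk - 1) * mesh$h
  seg <- mesh$nearest_segment[idx]
  gen <- mesh$tree$segments$generation[mesh$tree$segments$id == seg]
  list(max = max(spd), location = as.numeric(loc), generation = gen,
       q999 = as.numeric(quantile(spd, 0.999)))
}

#' Inlet-to-outlet pressure drop
#'
#' Face-area-weighted average gauge pressure over the fluid cells adjacent
#' to the velocity-inlet cap(s), with the pressure outlets pinned at 0 Pa.
#' The maximum wall-adjacent pressure is reported alongside.
#'
#' @param solution A [solve_steady()] result.
#' @return List: `drop` (Pa), `max_wall_pressure` (Pa).
#' @export
pressure_drop <- function(solution) {
  stopifnot(inherits(solution, "flow_solution"))
  mesh <- solution$mesh
  bc <- solution$bcs$table
  vel_patches <- which(bc$role == "velocity")
  if (length(vel_patches) == 0L) stop("no velocity inlet in this solution")
  dims <- mesh$dims
  ct <- array(mesh$celltype, dims)
  pr <- solution$p
  wsum <- 0; psum <- 0
  for (ax in 1:3) {
    lo <- lapply(dims, seq_len); hi <- lo
    lo[[ax]] <- seq_len(dims[ax] - 1L); hi[[ax]] <- 2:dims[ax]
    t0 <- do.call(`[`, c(list(ct), lo)); t1 <- do.call(`[`, c(list(ct), hi))
    p0 <- do.call(`[`, c(list(pr), lo)); p1 <- do.call(`[`, c(list(pr), hi))
    for (pk in vel_patches) {
      a <- t0 == 0L & t1 == pk
      b <- t1 == 0L & t0 == pk
      psum <- psum + sum(p0[a]) + sum(p1[b])
      wsum <- wsum + sum(a) + sum(b)
    }
  }
  if (wsum == 0) stop("velocity inlet has no adjacent fluid cells")
  fl <- mesh$celltype == 0L
  near_wall <- fl & mesh$phi > -1.5 * mesh$h
  list(drop = psum / wsum,
       max_wall_pressure = if (any(near_wall)) max(pr[array(near_wall, dims)])
                           else NA_real_)
}

#' Wall shear stress field
#'
#' Recovers the wall shear stress on wall-adjacent fluid cells from the
#' velocity component tangential to the wall, using a two-point one-sided
#' quadratic fit along the inward wall normal (exact for a parabolic
#' profile).  Wall normals and distances come from the signed-distance
#' field.  Cells within three lattice spacings of a velocity-inlet cap are
#' flagged `near_inlet`: the prescribed plug profile meets the no-slip wall
#' there with an unresolvable (mesh-divergent) shear singularity, so the
#' reported maximum excludes them.
#'
#' @param solution A [solve_steady()] result.
#' @param fluid A [fluid_properties()] (defaults to the one used to solve).
#' @return Data frame: wall-point coordinates, `wss` (Pa), `pressure` (Pa),
#'   `generation`, `near_inlet`; attribute `max_wss` (Pa, excluding
#'   near-inlet cells).
#' @export
wall_shear_stress <- function(solution, fluid = solution$fluid) {
  stopifnot(inherits(solution, "flow_solution"))
  mesh <- solution$mesh
  dims <- mesh$dims
  h <- mesh$h
  ct <- array(mesh$celltype, dims)
  solid <- ct < 0L
  near_solid <- array(FALSE, dims)
  for (ax in 1:3) for (d in c(-1L, 1L)) {
    idx <- lapply(dims, seq_len)
    idx[[ax]] <- pmin(pmax(seq_len(dims[ax]) + d, 1L), dims[ax])
    near_solid <- near_solid | do.call(`[`, c(list(solid), idx))
  }
  wallcells <- which(ct == 0L & near_solid)
  if (length(wallcells) == 0L) stop("no wall-adjacent fluid cells")
  ijk <- arrayInd(wallcells, dims)
  pts <- cbind(mesh$origin[1] + (ijk[, 1] - 1) * h,
               mesh$origin[2] + (ijk[, 2] - 1) * h,
               mesh$origin[3] + (ijk[, 3] - 1) * h)
  nrm <- .wall_normal(pts, mesh$tree, eps = h / 4) # outward
  dcell <- pmax(-.wall_phi(pts, mesh$tree, extend = mesh$ghost_extent),
                0.05 * h)
  wallpts <- pts + nrm * dcell
  # sample at fixed distances along the inward normal (interior points,
  # where interpolation is clean) and fit a parabola through u(0) = 0
  d1 <- h; d2 <- 2 * h
  v1 <- .interp_velocity(solution, wallpts - nrm * d1)
  v2 <- .interp_velocity(solution, wallpts - nrm * d2)
  tang <- function(v) {
    vn <- rowSums(v * nrm)
    vt <- v - vn * nrm
    sqrt(rowSums(vt^2))
  }
  u1 <- tang(v1); u2 <- tang(v2)
  # quadratic through (0,0),(d1,u1),(d2,u2): u'(0); linear where the deeper
  # sample leaves the fluid
  grad <- (u1 * d2^2 - u2 * d1^2) / (d1 * d2 * (d2 - d1))
  lin <- is.na(u2) & !is.na(u1)
  grad[lin] <- u1[lin] / d1
  grad[is.na(grad)] <- 0
  wss <- fluid$dynamic_viscosity * pmax(grad, 0)
  # flag the entrance sliver at each velocity-inlet cap
  bc <- solution$bcs$table
  caps <- mesh$patches
  near_inlet <- rep(FALSE, nrow(pts))
  for (pk in which(bc$role == "velocity")) {
    cp <- caps[pk, ]
    sdist <- (wallpts[, 1] - cp$cx) * cp$nx + (wallpts[, 2] - cp$cy) * cp$ny +
             (wallpts[, 3] - cp$cz) * cp$nz
    near_inlet <- near_inlet | abs(sdist) < 3 * h
  }
  seg <- mesh$nearest_segment[wallcells]
  gen <- mesh$tree$segments$generation[match(seg, mesh$tree$segments$id)]
  out <- data.frame(x = wallpts[, 1], y = wallpts[, 2], z = wallpts[, 3],
                    wss = wss, pressure = as.numeric(solution$p)[wallcells],
                    generation = gen, near_inlet = near_inlet)
  attr(out, "max_wss") <- if (all(near_inlet)) max(wss) else
    max(wss[!near_inlet])
  out
}

#' Trace velocity streamlines
#'
#' Integral curves of the interpolated velocity field (4th-order
#' Runge-Kutta, adaptive step 0.5 h / |v|), seeded on a disk just inside a
#' velocity-inlet cap, each labeled with its exit patch.  Per-bifurcation
#' split fractions are summarized from the exit patches.
#'
#' @param solution A [solve_steady()] result.
#' @param n_seeds Number of seeds (default 100).
#' @param seed_radius_fraction Seeding disk radius as a fraction of the cap
#'   radius (default 0.85; seeds hugging the wall move arbitrarily slowly).
#' @param seed RNG seed for the deterministic quasi-random seed layout.
#' @param max_steps Integration step cap per streamline.
#' @return An object of class `streamline_set`: list of polylines, exit
#'   patch per seed (`""` if stalled), arc lengths, and `exit_counts`.
#' @export
trace_streamlines <- function(solution, n_seeds = 100L,
                              seed_radius_fraction = 0.85, seed = 1L,
                              max_steps = 20000L) {
  stopifnot(inherits(solution, "flow_solution"))
  mesh <- solution$mesh
  bc <- solution$bcs$table
  caps <- mesh$patches
  vel <- which(bc$role == "velocity")
  if (length(vel) == 0L) stop("no velocity inlet to seed from")
  per <- ceiling(n_seeds / length(vel))
  seeds <- NULL
  set.seed(seed)
  for (pk in vel) {
    cp <- caps[pk, ]
    nrm <- c(cp$nx, cp$ny, cp$nz)
    ref <- if (abs(nrm[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    # sunflower (Fibonacci) layout: deterministic, quasi-uniform
    m <- seq_len(per)
    r <- cp$radius * seed_radius_fraction * sqrt((m - 0.5) / per)
    th <- 2 * pi * m * (1 + sqrt(5)) / 2
    base <- c(cp$cx, cp$cy, cp$cz) - nrm * 2.5 * mesh$h # just inside
    seeds <- rbind(seeds, cbind(base[1] + r * (cos(th) * e1[1] + sin(th) * e2[1]),
                                base[2] + r * (cos(th) * e1[2] + sin(th) * e2[2]),
                                base[3] + r * (cos(th) * e1[3] + sin(th) * e2[3])))
  }
  res <- .cpp_trace_streamlines(as.integer(mesh$dims), mesh$origin, mesh$h,
                                as.numeric(solution$uc), as.numeric(solution$vc),
                                as.numeric(solution$wc),
                                as.integer(mesh$celltype), seeds,
                                0.5, as.integer(max_steps), 4L)
  patch_names <- c("", caps$patch)
  exit <- patch_names[res$exit_patch + 1L]
  structure(list(lines = res$lines, exit_patch = exit, length = res$length,
                 seeds = seeds,
                 exit_counts = table(factor(exit, levels = patch_names))),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  cat(sprintf("Streamline set: %d seeds, %.1f%% reached an outlet\n",
              length(x$exit_patch), 100 * mean(x$exit_patch != "")))
  print(x$exit_counts)
  invisible(x)
}

#' Cross-case study report
#'
#' Collects per-case headline quantities into the study table, including the
#' embedded reference values for the three tabulated age groups and
#' age-monotonicity flags.
#'
#' @param cases Named list of per-case lists as produced by [run_study()]
#'   (each with `age`, `phase`, `solution`, `probe_set`).
#' @return An object of class `study_report`: data frame, one row per case.
#' @export
build_report <- function(cases) {
  if (length(cases) == 0L) stop("no cases to report")
  rows <- lapply(cases, function(cs) {
    sol <- cs$solution
    mv <- max_velocity(sol)
    pd <- pressure_drop(sol)
    ws <- wall_shear_stress(sol)
    data.frame(
      age = cs$age, phase = cs$phase,
      cells = sol$mesh$n_cells, converged = sol$converged,
      iterations = sol$iterations,
      max_velocity = mv$max, max_velocity_generation = mv$generation,
      pressure_drop = pd$drop, max_wall_pressure = pd$max_wall_pressure,
      max_wss = attr(ws, "max_wss"),
      mass_imbalance = sol$mass_imbalance,
      stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  # reference values (printed study results) for the anchor age groups
  ref <- .reference_results()
  rep$reference_max_velocity <- ref$max_velocity[
    match(paste(rep$age, rep$phase), paste(ref$age, ref$phase))]
  rep$reference_pressure_drop <- ref$pressure_drop[
    match(paste(rep$age, rep$phase), paste(ref$age, ref$phase))]
  rep$reference_max_wss <- ref$max_wss[
    match(paste(rep$age, rep$phase), paste(ref$age, ref$phase))]
  structure(rep, class = c("study_report", "data.frame"))
}

# Published headline results for the three anchor age groups.
.reference_results <- function() {
  data.frame(
    age = rep(c("infant", "child", "adult"), 2),
    phase = rep(c("inspiration", "expiration"), each = 3),
    max_velocity = c(2.22, 1.82, 1.41, 1.49, 1.12, 0.89),
    pressure_drop = c(11.15, 6.54, 3.71, 7.11, 3.45, 1.99),
    max_wss = c(1.74, 1.23, 0.66, 0.44, 0.28, 0.16),
    stringsAsFactors = FALSE)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (", nrow(x), "cases )\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
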