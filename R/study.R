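# Orchestration of the full multi-age, two-phase study, fixture generators,
# and the comparison harness against the published values.

#' Study configuration
#'
#' Validates and normalizes the configuration driving [run_study()].
#' Unknown keys are rejected.
#'
#' @param ages Character names (`"infant"`, `"child"`, `"adult"`) or numeric
#'   ages in years (interpolated profiles).
#' @param phases Subset of `c("inspiration", "expiration")`.
#' @param cells_per_dmin Lattice cells across the smallest airway diameter
#'   (sets the mesh spacing `h = D_min / cells_per_dmin`).
#' @param surface_resolution Surface edge length as a fraction of `D_min`.
#' @param n_layers Near-wall strata to tag.
#' @param settings A [solver_settings()].
#' @param outdir Output directory (`NULL`: no files written).
#' @param write_fields Also export solution/wall/streamline files per case.
#' @param seed Seed for the streamline seeding layout.
#' @return An object of class `study_config`.
#' @export
study_config <- function(ages = c("infant", "child", "adult"),
                         phases = c("inspiration", "expiration"),
                         cells_per_dmin = 8, surface_resolution = 0.1,
                         n_layers = 3L, settings = solver_settings(),
                         outdir = NULL, write_fields = FALSE, seed = 1L) {
  stopifnot(length(ages) >= 1,
            all(phases %in% c("inspiration", "expiration")),
            cells_per_dmin >= 3, surface_resolution > 0,
            inherits(settings, "solver_settings"))
  if (is.character(ages))
    stopifnot(all(ages %in% c("infant", "child", "adult")))
  structure(list(ages = ages, phases = phases,
                 cells_per_dmin = cells_per_dmin,
                 surface_resolution = surface_resolution,
                 n_layers = as.integer(n_layers), settings = settings,
                 outdir = outdir, write_fields = isTRUE(write_fields),
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' @param path YAML file; keys as in [study_config()] (solver settings under
#'   `settings:`).
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("ages", "phases", "cells_per_dmin", "surface_resolution",
             "n_layers", "settings", "outdir", "write_fields", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$settings)) y$settings <- do.call(solver_settings, y$settings)
  do.call(study_config, y)
}

#' Run the full study
#'
#' For every requested age and breathing phase: build the profile and
#' centerline tree, extract the surface, mesh it, apply the phase boundary
#' conditions, solve the steady laminar flow, and post-process.  A failing
#' case is recorded and the remaining cases still run.  With a fixed
#' configuration the pipeline is deterministic end to end.
#'
#' @param config A [study_config()].
#' @return A [build_report()] `study_report`; the per-case artifacts
#'   (solutions, probe sets, section tables) are attached as attribute
#'   `cases`, failures as attribute `failures`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cases <- list()
  failures <- list()
  for (age in config$ages) {
    prof <- if (is.character(age)) build_profile(age)
            else interpolate_profile(age)
    tree <- build_centerline_tree(prof)
    surf <- build_surface(tree, resolution = config$surface_resolution)
    dmin <- 2 * min(tree$segments$radius)
    mesh <- generate_volume_mesh(surf, dmin / config$cells_per_dmin,
                                 n_layers = config$n_layers)
    ps <- make_probe_set(tree)
    for (phase in config$phases) {
      key <- paste(prof$name, phase, sep = "_")
      res <- tryCatch({
        bc <- configure_phase(mesh, prof$pattern, phase)
        sol <- solve_steady(mesh, bc, settings = config$settings)
        list(age = prof$name, phase = phase, profile = prof, tree = tree,
             surface = surf, mesh = mesh, probe_set = ps, solution = sol,
             sections = section_stats(sol, ps))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[key]] <- conditionMessage(res)
      } else {
        cases[[key]] <- res
      }
    }
  }
  if (length(cases) == 0L)
    stop("every case failed; first error: ", failures[[1]])
  report <- build_report(cases)
  attr(report, "cases") <- cases
  attr(report, "failures") <- failures
  attr(report, "config") <- config
  if (!is.null(config$outdir)) .write_study_outputs(report, config)
  report
}

.write_study_outputs <- function(report, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(as.data.frame(report),
            file.path(config$outdir, "study_report.csv"), row.names = FALSE)
  cases <- attr(report, "cases")
  for (key in names(cases)) {
    cs <- cases[[key]]
    cdir <- file.path(config$outdir, key)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cs$sections, file.path(cdir, "sections.csv"), row.names = FALSE)
    meta <- list(age = cs$age, phase = cs$phase,
                 cells = cs$mesh$n_cells, h = cs$mesh$h,
                 converged = cs$solution$converged,
                 iterations = cs$solution$iterations,
                 mass_imbalance = cs$solution$mass_imbalance,
                 patch_flux = as.list(cs$solution$patch_flux))
    jsonlite::write_json(meta, file.path(cdir, "metadata.json"),
                         auto_unbox = TRUE, digits = NA)
    export_surface(cs$surface, file.path(cdir, "surface.stl"), "stl")
    if (config$write_fields) {
      export_solution(cs$solution, file.path(cdir, "solution.vtk"))
      export_mesh(cs$mesh, file.path(cdir, "mesh.vtk"))
      ws <- wall_shear_stress(cs$solution)
      export_wall_field(ws, file.path(cdir, "wall.vtk"))
      sl <- trace_streamlines(cs$solution, seed = config$seed)
      export_streamlines(sl, file.path(cdir, "streamlines.vtk"))
    }
  }
  invisible(config$outdir)
}

#' Fixture cases
#'
#' Small benchmark problems with attached analytic references:
#' `straight_tube` (Hagen-Poiseuille pressure gradient, wall shear stress
#' and centerline velocity), `single_bifurcation` (Poiseuille-network
#' oracle), `age_tree` (a study geometry).
#'
#' @param kind `"straight_tube"`, `"single_bifurcation"` or `"age_tree"`.
#' @param ... Parameters: `straight_tube`: `L`, `D` (m), `Q` (m^3/s);
#'   `single_bifurcation`: `L_parent`, `D_parent`, `L_child`, `D_child`,
#'   `angle`, `Q`; `age_tree`: `age` (name or years).
#' @return An object of class `fixture_case` with elements `kind`, `tree`,
#'   `params` and `reference` (analytic values where defined).
#' @export
make_fixture <- function(kind, ...) {
  prm <- list(...)
  fl <- fluid_properties()
  if (identical(kind, "straight_tube")) {
    L <- prm$L %||% 0.010; D <- prm$D %||% 0.002; Q <- prm$Q %||% 1e-6
    tree <- .straight_tube_tree(L, D)
    U <- mean_inlet_velocity(Q, D)
    ref <- list(
      pressure_drop = 128 * fl$dynamic_viscosity * L * Q / (pi * D^4),
      wss = 8 * fl$dynamic_viscosity * U / D,
      centerline_velocity = 2 * U, mean_velocity = U)
  } else if (identical(kind, "single_bifurcation")) {
    Lp <- prm$L_parent %||% 0.005; Dp <- prm$D_parent %||% 0.002
    Lc <- prm$L_child %||% 0.004; Dc <- prm$D_child %||% 0.0015
    ang <- prm$angle %||% 70; Q <- prm$Q %||% 1e-6
    tree <- .single_bifurcation_tree(Lp, Dp, Lc, Dc, angle = ang,
                                     outer_R = prm$outer_R %||% NA,
                                     carinal_r = prm$carinal_r %||% NA)
    ref <- list(network_drop = poiseuille_network_drop(tree, Q, fl)$total)
  } else if (identical(kind, "age_tree")) {
    age <- prm$age %||% "infant"
    prof <- if (is.character(age)) build_profile(age)
            else interpolate_profile(age)
    tree <- build_centerline_tree(prof)
    ref <- list(profile = prof)
  } else {
    stop("unknown fixture kind: ", kind)
  }
  structure(list(kind = kind, tree = tree, params = prm, reference = ref),
            class = "fixture_case")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare a study report against the published values
#'
#' Evaluates the analytic respiratory parameters (recomputed here) to their
#' printed precision, and the flow-derived quantities (maximum velocity,
#' inspiratory pressure drop) of any reference-age cases in the report
#' against the published values with the stated relative tolerance.  Cases
#' absent from the report are marked `unevaluated`, not failed.
#'
#' @param report A [run_study()] report.
#' @param cfd_tolerance Relative tolerance for flow-derived targets
#'   (default 0.20, appropriate for coarse desk-scale lattices; use 0.10
#'   for fine meshes).
#' @param wss_tolerance Relative tolerance for the wall-shear-stress maxima
#'   (default 0.30).
#' @param path Optional JSON file for the verdict table.
#' @return Data frame of targets: value, reference, tolerance, status.
#' @export
acceptance_harness <- function(report, cfd_tolerance = 0.20,
                               wss_tolerance = 0.30, path = NULL) {
  stopifnot(inherits(report, "study_report"))
  rows <- list()
  add <- function(name, value, ref, tol_abs) {
    status <- if (is.na(value)) "unevaluated"
              else if (abs(value - ref) <= tol_abs) "pass" else "fail"
    rows[[length(rows) + 1L]] <<- data.frame(
      target = name, value = value, reference = ref,
      tolerance = tol_abs, status = status, stringsAsFactors = FALSE)
  }
  # analytic respiratory parameters (printed precision)
  for (age in c("infant", "child", "adult")) {
    prof <- build_profile(age)
    q <- phase_flow_rates(prof$pattern)
    refq <- list(infant = c(3.51, 2.34), child = c(9.77, 5.75),
                 adult = c(18.90, 11.12))[[age]]
    refmv <- c(infant = 1404, child = 3620, adult = 7000)[[age]]
    refwo <- c(infant = 0.25, child = 0.34, adult = 0.44)[[age]]
    add(paste0("minute_ventilation_", age),
        minute_ventilation(prof$pattern), refmv, 0.5)
    add(paste0("insp_flow_", age), q[["inspiration"]], refq[1], 0.005)
    add(paste0("exp_flow_", age), q[["expiration"]], refq[2], 0.005)
    add(paste0("womersley_", age),
        womersley_number(prof$dims$D[1] * 1e-3, prof$pattern$respiratory_rate),
        refwo, 0.01)
  }
  # flow-derived targets from the report
  ref <- .reference_results()
  for (r in seq_len(nrow(ref))) {
    key <- report$age == ref$age[r] & report$phase == ref$phase[r]
    val <- if (any(key)) report$max_velocity[which(key)[1]] else NA_real_
    add(paste0("max_velocity_", ref$age[r], "_", substr(ref$phase[r], 1, 4)),
        val, ref$max_velocity[r], cfd_tolerance * ref$max_velocity[r])
    if (ref$phase[r] == "inspiration") {
      val <- if (any(key)) report$pressure_drop[which(key)[1]] else NA_real_
      add(paste0("pressure_drop_", ref$age[r], "_insp"),
          val, ref$pressure_drop[r], cfd_tolerance * ref$pressure_drop[r])
    }
    val <- if (any(key)) report$max_wss[which(key)[1]] else NA_real_
    add(paste0("max_wss_", ref$age[r], "_", substr(ref$phase[r], 1, 4)),
        val, ref$max_wss[r], wss_tolerance * ref$max_wss[r])
  }
  out <- do.call(rbind, rows)
  if (!is.null(path))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  out
}
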