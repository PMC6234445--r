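# Post-processing: section statistics, maxima, wall shear stress,
# streamlines and the cross-case report.

test_that("tube section statistics recover flux and the parabolic shape", {
  tube <- tube_fixture()
  ss <- section_stats(tube$solution, tube$probe_set)
  expect_equal(ss$flux, tube$Q, tolerance = 0.02)
  expect_equal(ss$center_speed / ss$avg_speed, 2.0, tolerance = 0.03)
  expect_equal(ss$area, pi * 0.001^2)
  # flux consistency: section average x area vs volumetric flow
  U <- mean_inlet_velocity(tube$Q, 0.002)
  expect_equal(ss$avg_speed, U, tolerance = 0.03)
})

test_that("tube wall shear stress matches the analytic value in the developed region", {
  tube <- tube_fixture()
  ws <- wall_shear_stress(tube$solution)
  ref <- tube$fixture$reference$wss
  developed <- abs(ws$x - 0.005) < 0.002
  expect_equal(mean(ws$wss[developed]), ref, tolerance = 0.05)
  # uniformity along the developed region
  expect_lt(sd(ws$wss[developed]) / mean(ws$wss[developed]), 0.05)
  expect_true(all(ws$wss >= 0))
})

test_that("zero-flow solution post-processes to zeros", {
  tube <- tube_fixture()
  bc0 <- bronchoflow:::.bc_flow_at(tube$mesh, "inlet", 0)
  sol0 <- solve_steady(tube$mesh, bc0)
  expect_equal(max_velocity(sol0)$max, 0)
  expect_equal(pressure_drop(sol0)$drop, 0)
  ws <- wall_shear_stress(sol0)
  expect_equal(max(ws$wss), 0)
})

test_that("probe metric is linear in the field and exact for uniform flow", {
  tube <- tube_fixture()
  sol <- tube$solution
  # synthetic uniform field of magnitude 1 on the same mesh
  uni <- sol
  uni$uc[] <- 1; uni$vc[] <- 0; uni$wc[] <- 0
  expect_equal(probe_average_velocity(uni, tube$probe_set), 1.0)
  # doubling the field doubles the metric
  dbl <- sol
  dbl$uc <- 2 * sol$uc; dbl$vc <- 2 * sol$vc; dbl$wc <- 2 * sol$wc
  expect_equal(probe_average_velocity(dbl, tube$probe_set),
               2 * probe_average_velocity(sol, tube$probe_set))
  # probe point outside the mesh errors
  bad <- tube$probe_set
  bad$path_points[1, ] <- c(1, 1, 1)
  expect_error(probe_average_velocity(sol, bad), "outside")
})

test_that("tube streamlines run straight through and exit the far cap", {
  tube <- tube_fixture()
  sl <- trace_streamlines(tube$solution, n_seeds = 50)
  expect_true(all(sl$exit_patch == "outlet_1"))
  expect_true(all(sl$length > 0.009))
  # lateral wander stays small in unidirectional flow
  wander <- vapply(sl$lines, function(L) max(abs(L[, 2] - L[1, 2])), 0)
  expect_lt(max(wander), 2e-4)
  f <- tempfile(fileext = ".vtk")
  export_streamlines(sl, f)
  expect_match(readLines(f, n = 4)[4], "POLYDATA")
})

test_that("solution and wall-field exports are well-formed VTK", {
  tube <- tube_fixture()
  f1 <- tempfile(fileext = ".vtk")
  export_solution(tube$solution, f1)
  txt <- readLines(f1)
  expect_match(txt[4], "STRUCTURED_POINTS")
  n <- prod(tube$mesh$dims)
  expect_equal(sum(txt == "LOOKUP_TABLE default"), 2)
  f2 <- tempfile(fileext = ".vtk")
  export_wall_field(wall_shear_stress(tube$solution), f2)
  expect_match(readLines(f2, n = 4)[4], "POLYDATA")
})

test_that("the study report table carries references and ordering flags", {
  rep <- study_fixture()
  expect_s3_class(rep, "study_report")
  expect_equal(nrow(rep), 6)
  expect_setequal(rep$phase, c("inspiration", "expiration"))
  expect_equal(rep$reference_max_velocity[
    rep$age == "infant" & rep$phase == "inspiration"], 2.22)
  expect_error(build_report(list()), "no cases")
})
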