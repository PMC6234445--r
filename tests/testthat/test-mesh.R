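# Volume meshing, grid convergence index, and the mesh-independence
# selection logic (with synthetic solve functions; real-solve ladders are
# exercised in the acceptance suite).

test_that("cylinder volume mesh captures the enclosed volume and patch areas", {
  fx <- make_fixture("straight_tube", L = 0.010, D = 0.002)
  surf <- build_surface(fx$tree)
  mesh <- generate_volume_mesh(surf, 0.002 / 10, n_layers = 3L)
  expect_equal(mesh$volume, pi * 0.001^2 * 0.010, tolerance = 0.02)
  schk <- check_surface(surf)
  for (pk in c("inlet", "outlet_1")) {
    expect_equal(mesh$patches$open_area[mesh$patches$patch == pk],
                 unname(schk$cap_areas_projected[pk]), tolerance = 0.05,
                 info = pk)
  }
  # near-wall strata: n_layers distinct bands adjacent to the wall
  expect_gte(length(setdiff(unique(mesh$layer), 0L)), 3L)
  inner <- mesh$layer == 1L
  expect_true(all(mesh$phi[inner] > -1.01 * mesh$h))
  # tetrahedral decomposition is conforming and complete
  tet <- mesh_tetrahedra(mesh)
  expect_equal(nrow(tet$tetrahedra), mesh$n_cells)
  expect_equal(6 * mesh$n_fluid_cells, mesh$n_cells)
})

test_that("halving the cell size grows the cell count by a 3D factor", {
  fx <- make_fixture("straight_tube", L = 0.008, D = 0.002)
  surf <- build_surface(fx$tree, resolution = 0.15)
  coarse <- generate_volume_mesh(surf, 0.002 / 5)
  fine <- generate_volume_mesh(surf, 0.002 / 10)
  ratio <- fine$n_cells / coarse$n_cells
  expect_gte(ratio, 4); expect_lte(ratio, 16)
})

test_that("grid convergence index follows the Richardson form", {
  expect_equal(grid_convergence_index(1, 1, 2, 2), 0)
  expect_equal(grid_convergence_index(1.01, 1.00, 2, 2),
               1.25 * 0.01 / 3, tolerance = 1e-12)
  # linear in the solution difference
  g1 <- grid_convergence_index(1.02, 1.00, 1.5, 2)
  g2 <- grid_convergence_index(1.04, 1.00, 1.5, 2)
  expect_equal(g2 / g1, 2, tolerance = 1e-10)
  expect_error(grid_convergence_index(1, 0, 2, 2), "zero")
  expect_error(grid_convergence_index(1, 1, 0.9, 2))
})

test_that("mesh-independence selection picks the coarsest level within tolerance", {
  fx <- make_fixture("straight_tube", L = 0.008, D = 0.002)
  surf <- build_surface(fx$tree, resolution = 0.15)
  ladder <- 0.002 / c(4, 5, 6, 7)
  # synthetic metric sequence keyed by cell size
  metric_of <- function(vals) {
    i <- 0
    function(mesh) { i <<- i + 1; vals[i] }
  }
  st <- mesh_independence_study(surf, ladder,
                                metric_of(c(1.10, 1.01, 1.005, 1.0049)),
                                NULL, tolerance = 0.003)
  expect_equal(st$selected, 3) # changes: 8.2%, 0.5%, 0.02%
  expect_true(st$tolerance_met)
  st0 <- mesh_independence_study(surf, ladder[1:2], metric_of(c(5, 5)),
                                 NULL, tolerance = 0.003)
  expect_equal(st0$selected, 1) # constant metric: coarsest level
  expect_warning(
    stf <- mesh_independence_study(surf, ladder[1:3], metric_of(c(1, 1.5, 2)),
                                   NULL, tolerance = 0.003),
    "finest")
  expect_equal(stf$selected, 3)
  expect_false(stf$tolerance_met)
  st9 <- mesh_independence_study(surf, ladder[1:2], metric_of(c(1, 1.5)),
                                 NULL, tolerance = 0.999)
  expect_equal(st9$selected, 1) # vacuous tolerance
})

test_that("mesh export round-trips through MSH and writes valid VTK", {
  fx <- make_fixture("straight_tube", L = 0.006, D = 0.002)
  surf <- build_surface(fx$tree, resolution = 0.15)
  mesh <- generate_volume_mesh(surf, 0.002 / 5)
  msh <- tempfile(fileext = ".msh")
  export_mesh(mesh, msh, "msh")
  back <- import_msh(msh)
  tet <- mesh_tetrahedra(mesh)
  expect_equal(nrow(back$tetrahedra), nrow(tet$tetrahedra))
  expect_equal(back$vertices, tet$vertices, tolerance = 1e-12)
  vtk <- tempfile(fileext = ".vtk")
  export_mesh(mesh, vtk, "vtk")
  txt <- readLines(vtk, n = 6)
  expect_match(txt[4], "UNSTRUCTURED_GRID")
})
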