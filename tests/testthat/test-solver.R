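# Steady laminar solver: analytic Poiseuille verification, conservation,
# determinism, degenerate inputs, and the creeping-flow network bracket.

test_that("tube solve converges with exact global mass balance", {
  tube <- tube_fixture()
  sol <- tube$solution
  expect_true(sol$converged)
  expect_lt(sol$mass_imbalance, 0.005)
  expect_equal(unname(sol$patch_flux["inlet"]), tube$Q, tolerance = 1e-9)
  expect_equal(unname(sol$patch_flux["outlet_1"]), -tube$Q, tolerance = 1e-6)
  # all residuals below the convergence criterion
  final <- sol$residuals[nrow(sol$residuals), ]
  expect_true(all(final < sol$settings$residual_tolerance))
})

test_that("tube solution matches the parabolic Poiseuille profile", {
  tube <- tube_fixture()
  sol <- tube$solution
  U <- mean_inlet_velocity(tube$Q, 0.002)
  # developed centerline velocity = 2 x mean
  expect_equal(probe_average_velocity(sol, tube$probe_set), 2 * U,
               tolerance = 0.03)
  # developed-region pressure gradient vs Hagen-Poiseuille
  hp <- tube$fixture$reference$pressure_drop
  expect_equal(tube_gradient_drop(tube), hp, tolerance = 0.05)
  # total inlet-to-outlet drop exceeds the ideal fully developed value
  expect_gt(pressure_drop(sol)$drop, 0.95 * hp)
})

test_that("zero inlet flow yields identically zero fields", {
  tube <- tube_fixture()
  bc0 <- bronchoflow:::.bc_flow_at(tube$mesh, "inlet", 0)
  sol0 <- solve_steady(tube$mesh, bc0)
  expect_true(sol0$converged)
  expect_equal(max(abs(sol0$speed)), 0)
  expect_equal(max(abs(sol0$p)), 0)
})

test_that("the solve is bit-deterministic for fixed mesh and settings", {
  fx <- make_fixture("straight_tube", L = 0.005, D = 0.002, Q = 2e-8)
  surf <- build_surface(fx$tree, resolution = 0.15)
  mesh <- generate_volume_mesh(surf, 0.002 / 5)
  bc <- bronchoflow:::.bc_flow_at(mesh, "inlet", 2e-8)
  s1 <- solve_steady(mesh, bc)
  s2 <- solve_steady(mesh, bc)
  expect_identical(s1$uc, s2$uc)
  expect_identical(s1$p, s2$p)
  expect_identical(s1$iterations, s2$iterations)
})

test_that("creeping flow through a single bifurcation brackets the network oracle", {
  fx <- make_fixture("single_bifurcation", L_parent = 0.004, D_parent = 0.0012,
                     L_child = 0.003, D_child = 0.001, Q = 1e-8)
  surf <- build_surface(fx$tree)
  mesh <- generate_volume_mesh(surf, 0.0012 / 7)
  bc <- bronchoflow:::.bc_flow_at(mesh, "inlet", 1e-8)
  creeping <- fluid_properties(dynamic_viscosity = 1.7894e-5 * 1e6)
  sol <- solve_steady(mesh, bc, fluid = creeping)
  expect_true(sol$converged)
  oracle <- poiseuille_network_drop(fx$tree, 1e-8, creeping)$total
  expect_equal(pressure_drop(sol)$drop, oracle, tolerance = 0.10)
  # symmetric geometry, symmetric boundary conditions: equal outlet split
  out <- sol$patch_flux[c("outlet_1", "outlet_2")]
  expect_equal(unname(out[1]), unname(out[2]), tolerance = 1e-3)
})

test_that("phase boundary conditions follow the symmetric Weibel split", {
  cs <- infant_fixture()
  mesh <- cs$mesh
  pat <- cs$profile$pattern
  insp <- configure_phase(mesh, pat, "inspiration")
  expect_equal(sum(insp$table$role == "velocity"), 1)
  expect_equal(sum(insp$table$role == "pressure"), 8)
  expect_equal(insp$table$Q[1], branch_flow_rate(3.51, 6))
  expect_equal(insp$table$speed[1], 1.16, tolerance = 0.01)
  exp_ <- configure_phase(mesh, pat, "expiration")
  expect_equal(sum(exp_$table$role == "velocity"), 8)
  # total prescribed expiratory inflow equals the G6 branch flow
  expect_equal(sum(exp_$table$Q), branch_flow_rate(2.34, 6), tolerance = 1e-12)
  # network oracle: doubling flow doubles every drop
  nd1 <- poiseuille_network_drop(cs$tree, 1e-7)
  nd2 <- poiseuille_network_drop(cs$tree, 2e-7)
  expect_equal(nd2$total, 2 * nd1$total)
  expect_equal(nd2$per_segment$drop, 2 * nd1$per_segment$drop)
})

test_that("network oracle reproduces hand-computed drops", {
  # single tube: direct Hagen-Poiseuille evaluation
  fx <- make_fixture("straight_tube", L = 0.010, D = 0.002, Q = 1e-6)
  nd <- poiseuille_network_drop(fx$tree, 1e-6)
  expect_equal(nd$total, 0.4557, tolerance = 1e-3)
  # infant inspiratory G6-G9 path: per-generation drops from the tables
  tr <- build_centerline_tree(build_profile("infant"))
  nd <- poiseuille_network_drop(tr, branch_flow_rate(3.51, 6))
  per <- nd$per_segment$drop[match(c(1, 2, 4, 8), nd$per_segment$segment)]
  expect_equal(per, c(2.33, 1.47, 1.73, 1.35), tolerance = 0.005)
  expect_equal(nd$total, 6.89, tolerance = 0.01)
})
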