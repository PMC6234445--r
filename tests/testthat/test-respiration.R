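# Respiratory flow parameters: embedded table values and the conversion
# chain from breathing pattern to branch velocities and dimensionless
# numbers.

test_that("minute ventilation and phase flow rates reproduce the tabulated values", {
  ref <- list(
    infant = list(mv = 1404, q = c(3.51, 2.34)),
    child  = list(mv = 3620, q = c(9.77, 5.75)),
    adult  = list(mv = 7000, q = c(18.90, 11.12)))
  for (age in names(ref)) {
    pat <- build_profile(age)$pattern
    expect_equal(minute_ventilation(pat), ref[[age]]$mv)
    q <- phase_flow_rates(pat)
    expect_equal(round(unname(q), 2), ref[[age]]$q,
                 info = paste("phase flows for", age))
    expect_gt(q[["inspiration"]], q[["expiration"]]) # t_e > t_i throughout
  }
  # zero tidal volume
  expect_equal(minute_ventilation(breathing_pattern(0, 10, c(1, 2))), 0)
  # symmetric phases: both rates are twice the minute ventilation
  qs <- phase_flow_rates(breathing_pattern(100, 10, c(1, 1)))
  expect_equal(unname(qs[1]), unname(qs[2]))
  expect_equal(unname(qs[1]), 2 * 100 * 10 / 1000)
})

test_that("time-weighted phase flows conserve the minute ventilation exactly", {
  for (age in c("infant", "child", "adult")) {
    pat <- build_profile(age)$pattern
    q <- phase_flow_rates(pat)
    ti <- pat$ie_ratio[1]; te <- pat$ie_ratio[2]
    mv <- minute_ventilation(pat) / 1000
    expect_equal(q[["inspiration"]] * ti / (ti + te), mv)
    expect_equal(q[["expiration"]] * te / (ti + te), mv)
  }
})

test_that("branch flow halves per generation and sums back to the total", {
  expect_equal(branch_flow_rate(12, 0), 12e-3 / 60) # trachea identity
  for (g in c(3, 6, 9)) {
    per_branch <- branch_flow_rate(18.90, g)
    expect_equal(per_branch * 2^g, 18.90e-3 / 60)
  }
  expect_error(branch_flow_rate(1, -1), "non-negative")
  # derived example: adult inspiratory G6 branch flow
  expect_equal(branch_flow_rate(18.90, 6), 4.9219e-6, tolerance = 1e-4)
  expect_equal(branch_flow_rate(3.51, 6), 9.1406e-7, tolerance = 1e-4)
})

test_that("mean inlet velocity and Reynolds numbers match the derived values", {
  expect_equal(mean_inlet_velocity(pi / 4 * 1e-6, 1e-3), 1.0)
  u_inf <- mean_inlet_velocity(branch_flow_rate(3.51, 6), 1.0e-3)
  u_ad <- mean_inlet_velocity(branch_flow_rate(18.90, 6), 2.8e-3)
  expect_equal(u_inf, 1.16, tolerance = 0.01)
  expect_equal(u_ad, 0.80, tolerance = 0.01)
  expect_equal(reynolds_number(u_inf, 1.0e-3), 80, tolerance = 0.01)
  expect_equal(reynolds_number(u_ad, 2.8e-3), 153, tolerance = 0.01)
  # definition identity
  fl <- fluid_properties()
  expect_equal(reynolds_number(fl$dynamic_viscosity / (fl$density * 0.002),
                               0.002), 1.0)
})

test_that("radius-based Womersley numbers reproduce the printed inlet values", {
  expect_equal(womersley_number(1.0e-3, 36), 0.25, tolerance = 0.01 / 0.25)
  expect_equal(womersley_number(1.8e-3, 20), 0.34, tolerance = 0.01 / 0.34)
  expect_equal(womersley_number(2.8e-3, 14), 0.44, tolerance = 0.01 / 0.44)
  # all three to two decimals pins the radius (not diameter) definition
  expect_equal(round(womersley_number(1.0e-3, 36), 2), 0.25)
  expect_equal(round(womersley_number(1.8e-3, 20), 2), 0.34)
  expect_equal(round(womersley_number(2.8e-3, 14), 2), 0.44)
})
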