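# Age profiles, interpolation, centerline trees and probe geometry.

test_that("embedded profiles carry the tabulated dimensions and validate", {
  p <- build_profile("infant")
  expect_equal(p$dims$generation, 6:9)
  expect_equal(unlist(p$dims[1, c("L", "D", "R", "r")]),
               c(L = 3.5, D = 1.0, R = 1.8, r = 0.09))
  a <- build_profile("adult")
  expect_equal(unlist(a$dims[4, c("L", "D")]), c(L = 5.3, D = 1.5))
  expect_true(all(is.na(a$dims[4, c("R", "r")])))
  expect_equal(a$bifurcation_angle, 70)
  expect_error(build_profile("dog"), "unknown age-group")
  # monotone growth: infant < child < adult in L and D per generation
  ch <- build_profile("child")
  expect_true(all(p$dims$L < ch$dims$L & ch$dims$L < a$dims$L))
  expect_true(all(p$dims$D < ch$dims$D & ch$dims$D < a$dims$D))
  # carinal radius always below the airway radius
  for (q in list(p, ch, a))
    expect_true(all(q$dims$r < q$dims$D / 2, na.rm = TRUE))
})

test_that("age interpolation is exact at anchors, linear between, bounded", {
  expect_equal(interpolate_profile(5)$dims, build_profile("child")$dims)
  expect_equal(interpolate_profile(0.5)$dims, build_profile("infant")$dims)
  mid <- interpolate_profile(15)
  expect_equal(mid$dims$D[1], 2.3) # halfway child (1.8) to adult (2.8)
  expect_equal(mid$pattern$tidal_volume, (181 + 500) / 2)
  expect_error(interpolate_profile(30), "0.5, 25")
  expect_error(interpolate_profile(0.1), "0.5, 25")
  # diameters remain strictly decreasing at arbitrary ages
  for (age in c(1.7, 3, 9, 21)) {
    d <- interpolate_profile(age)$dims$D
    expect_true(all(diff(d) < 0), info = paste("age", age))
  }
})

test_that("centerline tree is a planar symmetric binary tree with the set angle", {
  for (age in c("infant", "adult")) {
    p <- build_profile(age)
    tr <- build_centerline_tree(p)
    s <- tr$segments
    expect_equal(nrow(s), 15)
    expect_equal(sum(s$terminal), 8)
    # binary: every non-terminal segment has exactly two children
    for (id in s$id[!s$terminal])
      expect_equal(sum(s$parent == id), 2)
    # planar
    expect_equal(max(abs(c(s$az, s$bz))), 0)
    # unit directions, child angle = bifurcation angle
    expect_equal(rowSums(s[, c("dx", "dy", "dz")]^2), rep(1, 15))
    for (id in s$id[!s$terminal]) {
      kids <- s[s$parent == id, ]
      cosang <- sum(kids[1, c("dx", "dy", "dz")] * kids[2, c("dx", "dy", "dz")])
      expect_equal(acos(cosang) * 180 / pi, 70, tolerance = 1e-8)
    }
    # mm -> m conversion: radii are half the tabulated diameters
    expect_equal(sort(unique(s$radius)), sort(p$dims$D) * 1e-3 / 2)
  }
  # infant root-to-tip axial path length: sum of the four lengths
  tr <- build_centerline_tree(build_profile("infant"))
  s <- tr$segments
  len <- 0; id <- 1
  while (length(id) == 1) {
    len <- len + s$L[s$id == id]
    id <- s$id[s$parent == id & s$side == "right"]
  }
  expect_equal(len * 1e3, 3.5 + 2.9 + 2.5 + 2.1)
})

test_that("probe set has one mid-section per segment and an interior right-G7 path", {
  tr <- build_centerline_tree(build_profile("infant"))
  ps <- make_probe_set(tr)
  expect_equal(nrow(ps$mid_sections), 15)
  expect_equal(nrow(ps$path_points), 5)
  s <- tr$segments
  g7r <- s[s$generation == 7 & s$side == "right", ]
  expect_equal(ps$path_segment, g7r$id)
  expect_lt(g7r$by, 0) # "right" deviates toward negative y
  # path points lie on the segment axis, strictly inside
  for (i in 1:5) {
    ap <- ps$path_points[i, ] - c(g7r$ax, g7r$ay, g7r$az)
    t <- sum(ap * c(g7r$dx, g7r$dy, g7r$dz))
    expect_gt(t, 0); expect_lt(t, g7r$L)
    expect_lt(sqrt(max(sum(ap^2) - t^2, 0)), 1e-9) # on-axis
  }
  # G6 mid-section passes through the root-axis midpoint
  m6 <- ps$mid_sections[1, ]
  expect_equal(c(m6$cx, m6$cy, m6$cz), c(s$L[1] / 2, 0, 0))
})
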