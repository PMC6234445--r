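# Surface extraction: watertightness, dimensional fidelity, symmetry,
# labeling, export round trips.

test_that("cylinder surface reproduces analytic area and volume", {
  fx <- make_fixture("straight_tube", L = 0.010, D = 0.002)
  surf <- build_surface(fx$tree)
  chk <- check_surface(surf)
  expect_true(chk$closed_manifold)
  expect_equal(chk$patch_areas[["wall"]], pi * 0.002 * 0.010, tolerance = 0.01)
  expect_equal(chk$volume, pi * 0.001^2 * 0.010, tolerance = 0.02)
  expect_equal(unname(chk$cap_areas_projected["inlet"]), pi * 0.001^2,
               tolerance = 0.03)
})

test_that("age-group surfaces are closed manifolds with correctly sized sections", {
  for (age in c("infant", "adult")) {
    p <- build_profile(age)
    tr <- build_centerline_tree(p)
    surf <- build_surface(tr)
    chk <- check_surface(surf)
    expect_true(chk$closed_manifold, info = age)
    expect_gt(chk$volume, 0)
    expect_setequal(unique(surf$patch),
                    c("wall", "inlet", paste0("outlet_", 1:8)))
    # dimensional fidelity: mid-generation section areas via the implicit
    # model: radial distance of surface vertices near each mid-plane
    s <- tr$segments
    for (r in c(1, 2, 8)) {
      sg <- s[r, ]
      mid <- c(sg$ax, sg$ay, sg$az) + sg$L / 2 * c(sg$dx, sg$dy, sg$dz)
      rel <- sweep(surf$vertices, 2, mid)
      t <- rel %*% c(sg$dx, sg$dy, sg$dz)
      near <- abs(t) < surf$spacing
      rad <- sqrt(rowSums(rel[near, , drop = FALSE]^2) - t[near]^2)
      area_ratio <- (median(rad) / sg$radius)^2
      expect_equal(area_ratio, 1, tolerance = 0.02,
                   info = paste(age, "segment", r))
    }
    # mirror symmetry: reflected vertices still lie on the implicit surface
    refl <- surf$vertices; refl[, 2] <- -refl[, 2]
    phi <- bronchoflow:::.airway_phi(refl, tr)$phi
    expect_lt(quantile(abs(phi), 0.99), surf$spacing)
  }
})

test_that("surface export round-trips through STL and VTK polydata", {
  fx <- make_fixture("straight_tube", L = 0.006, D = 0.002)
  surf <- build_surface(fx$tree, resolution = 0.15)
  stl <- tempfile(fileext = ".stl")
  export_surface(surf, stl, "stl")
  back <- import_surface(stl, "stl")
  expect_equal(nrow(back$triangles), nrow(surf$triangles))
  # float32 round trip of coordinates
  a <- surf$vertices[surf$triangles[, 1], ]
  expect_equal(back$vertices[seq(1, nrow(back$vertices), by = 3), ], a,
               tolerance = 1e-5)
  vtk <- tempfile(fileext = ".vtk")
  export_surface(surf, vtk, "vtk")
  back2 <- import_surface(vtk, "vtk")
  expect_equal(back2$vertices, surf$vertices)
  expect_equal(back2$triangles, surf$triangles)
  expect_equal(sum(back2$patch == 0L), sum(surf$patch == "wall"))
  expect_true(file.exists(paste0(stl, ".json")))
  expect_error(export_surface(surf, tempfile(), "obj"))
})

test_that("STL facet normals are outward-consistent", {
  fx <- make_fixture("straight_tube", L = 0.006, D = 0.002)
  surf <- build_surface(fx$tree, resolution = 0.15)
  # signed volume positive means consistently outward-oriented triangles
  expect_gt(check_surface(surf)$volume, 0)
})
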