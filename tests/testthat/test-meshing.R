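test_that("the digital ball meshes to the analytic volume, closed and genus 0", {
  fx <- make_fixture("digital-ball-20")
  m <- mask_to_mesh(fx$mask, resolution = 1, origin = c(0, 0, 0))
  analytic <- 4 / 3 * pi * 20^3
  expect_lt(abs(mesh_volume(m) - analytic) / analytic, 0.02)
  expect_true(edges_closed(m$faces))
  rep <- validate_mesh(m, check_self_intersections = FALSE)
  expect_true(rep$watertight)
  expect_equal(rep$components, 1)
  expect_equal(rep$euler_characteristic, 2)
  expect_gt(mesh_volume(m), 0)   # outward orientation
})

test_that("a single voxel yields the smallest closed isosurface", {
  m <- mask_to_mesh(array(TRUE, dim = c(1, 1, 1)), resolution = 1)
  rep <- validate_mesh(m)
  expect_true(rep$watertight)
  expect_equal(rep$components, 1)
  expect_equal(rep$euler_characteristic, 2)
  # tetrahedral marching encloses half a voxel around an isolated sample
  expect_gt(mesh_volume(m), 0.3)
  expect_lte(mesh_volume(m), 1.0)
  expect_error(mask_to_mesh(array(FALSE, dim = c(2, 2, 2))), "empty")
})

test_that("smoothing reduces the staircase and respects the volume guard", {
  fx <- make_fixture("digital-ball-20")
  m <- mask_to_mesh(fx$mask, resolution = 1, origin = c(0, 0, 0))
  v0 <- mesh_volume(m)
  sm <- smooth_and_decimate(m, smooth_iters = 10L, decim_fraction = 1)
  expect_identical(dim(sm$faces), dim(m$faces))   # fraction 1: no decimation
  spread <- function(V) {
    r <- sqrt(rowSums(sweep(V, 2, fx$centre)^2))
    max(abs(r - mean(r)))
  }
  expect_lt(spread(sm$vertices), spread(m$vertices))
  expect_lt(abs(mesh_volume(sm) - v0) / v0, 0.02 + 1e-9)

  # identity configuration
  id <- smooth_and_decimate(m, smooth_iters = 0L, decim_fraction = 1)
  expect_identical(id$vertices, m$vertices)
  expect_identical(id$faces, m$faces)
})

test_that("decimation halves the face count within the volume guard, staying watertight", {
  fx <- make_fixture("digital-ball-20")
  m <- mask_to_mesh(fx$mask, resolution = 1, origin = c(0, 0, 0))
  d <- smooth_and_decimate(m, smooth_iters = 5L, decim_fraction = 0.5)
  expect_lte(nrow(d$faces), 0.5 * nrow(m$faces))
  expect_lt(abs(mesh_volume(d) - mesh_volume(m)) / mesh_volume(m), 0.04)
  rep <- validate_mesh(d)
  expect_true(rep$watertight)
  expect_equal(rep$components, 1)
  expect_equal(rep$self_intersections, 0)
})

test_that("validate_mesh detects a boundary edge from one deleted triangle", {
  fx <- make_fixture("digital-ball-20")
  m <- mask_to_mesh(fx$mask, resolution = 1, origin = c(0, 0, 0))
  broken <- m
  broken$faces <- broken$faces[-10, ]
  expect_false(validate_mesh(broken, check_self_intersections = FALSE)$watertight)
})

test_that("inner surfaces nest inside outer surfaces and the full pipeline validates", {
  s20 <- make_fixture("bundle-20")
  g <- rasterize_capsules(s20, 0.1)
  g <- grow_fibres(g, s20, growth_policy("uniform", 1000L, cap_factor = 1.5, seed = 5))
  g <- erode_inner(g, s20, g_target = 0.7)
  kf <- attr(g, "erosion")$kf
  myelinated <- which(kf >= 1)
  ids <- utils::head(myelinated, 6)
  outer <- fibre_meshes(g, "outer", fibres = ids)
  inner <- fibre_meshes(g, "inner", fibres = ids)
  for (nm in names(inner)) {
    expect_lt(mesh_volume(inner[[nm]]), mesh_volume(outer[[nm]]))
    rep <- validate_mesh(outer[[nm]])
    expect_true(rep$watertight)
    expect_true(rep$oriented)
    expect_equal(rep$components, 1)
    expect_equal(rep$self_intersections, 0)
  }

  # mesh-based vs voxel-based myelin volume (per-fibre shells, 6 fibres)
  vox_myelin <- sum(tabulate(g$owner[g$owner > 0], g$nfib)[ids] -
                      tabulate(g$inner[g$inner > 0], g$nfib)[ids]) * g$res^3
  mesh_myelin <- sum(vapply(names(inner), function(nm)
    mesh_volume(outer[[nm]]) - mesh_volume(inner[[nm]]), numeric(1)))
  expect_lt(abs(mesh_myelin - vox_myelin) / vox_myelin, 0.12)
})
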