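test_that("rasterization recovers the analytic capsule volume and keeps owners disjoint", {
  f <- fibre_skeleton(rbind(c(0, 0, 0), c(0, 0, 10)), c(1, 1), id = 1)
  s <- substrate(list(f), rbind(c(-2, -2, -2), c(2, 2, 12)))
  grid <- rasterize_capsules(s, 0.1)
  vol <- sum(grid$owner > 0) * grid$res^3
  analytic <- pi * 1^2 * 10 + 4 / 3 * pi   # cylinder + two hemispherical caps
  expect_lt(abs(vol - analytic) / analytic, 0.03)

  # empty substrate: all voxels unclaimed
  s0 <- substrate(list(), rbind(c(0, 0, 0), c(2, 2, 2)))
  g0 <- rasterize_capsules(s0, 0.1)
  expect_true(all(g0$owner == 0))

  # two disjoint fibres: ownership is single-valued so masks are disjoint
  f2 <- fibre_skeleton(rbind(c(0, 3, 0), c(0, 3, 10)), c(1, 1), id = 2)
  s2 <- substrate(list(f, f2), rbind(c(-2, -2, -2), c(2, 5, 12)))
  g2 <- rasterize_capsules(s2, 0.1)
  expect_setequal(unique(g2$owner[g2$owner > 0]), c(1L, 2L))

  # resolution coarser than a fifth of the smallest diameter errors
  expect_error(rasterize_capsules(s, 0.5), "5 voxels")
})

test_that("growth respects the iteration budget, the radius cap, and monotone densification", {
  f <- fibre_skeleton(rbind(c(0, 0, 0), c(0, 0, 10)), c(1, 1), id = 1,
                      target_radii = c(1.5, 1.5))
  s <- substrate(list(f), rbind(c(-3, -3, -1), c(3, 3, 11)))
  grid <- rasterize_capsules(s, 0.1)
  before <- sum(grid$owner > 0)
  grid <- grow_fibres(grid, s, growth_policy("uniform", iterations = 0L, seed = 1))
  expect_equal(sum(grid$owner > 0), before)   # 0 iterations: unchanged

  # generous budget: the isolated fibre fills its cap radius (1.5 um)
  grid <- grow_fibres(grid, s, growth_policy("uniform", iterations = 100L,
                                             cap_factor = 1.0, seed = 1))
  vol <- sum(grid$owner > 0) * grid$res^3
  analytic <- pi * 1.5^2 * 10 + 4 / 3 * pi * 1.5^3
  expect_lt(abs(vol - analytic) / analytic, 0.05)

  # dense toy bundle: FVF non-decreasing layer by layer, identity holds throughout
  s20 <- make_fixture("bundle-20")
  g <- rasterize_capsules(s20, 0.1)
  fvf_prev <- volume_fractions(g)[["FVF"]]
  for (layer in 1:6) {
    g <- grow_fibres(g, s20, growth_policy("uniform", iterations = 1L,
                                           cap_factor = 1.5, seed = layer))
    vf <- volume_fractions(g)
    expect_gte(vf[["FVF"]], fvf_prev)
    expect_equal(vf[["FVF"]] + vf[["EVF"]], 1)
    fvf_prev <- vf[["FVF"]]
  }
})

test_that("growth is reproducible under a fixed seed", {
  s20 <- make_fixture("bundle-20")
  run <- function() {
    g <- rasterize_capsules(s20, 0.1)
    g <- grow_fibres(g, s20, growth_policy("random", iterations = 12L,
                                           cap_factor = 1.5, seed = 99))
    g$owner
  }
  expect_identical(run(), run())
})

test_that("radius modulation rewrites radii within bounds and shows up in the grown profile", {
  f <- fibre_skeleton(cbind(0, 0, seq(0, 12, by = 1)), rep(1, 13), id = 1)
  same <- radius_modulation(f, rep(1, 13))
  expect_equal(same$radii, f$radii)

  osc <- radius_modulation(f, list(amplitude = 0.5, period = 4))
  expect_true(all(osc$radii >= 0.5 - 1e-9 & osc$radii <= 1.5 + 1e-9))

  expect_error(radius_modulation(f, c(1, -0.2)), "non-positive")

  # periodic 1 um / 2 um pattern (two capsules per level): the grown fibre's
  # radius profile oscillates with the prescribed period
  alt <- radius_modulation(f, rep(c(1, 1, 2, 2), length.out = 13))
  s <- substrate(list(alt), rbind(c(-3, -3, -1), c(3, 3, 13)))
  attr(s, "reference") <- s
  grid <- rasterize_capsules(s, 0.1)
  grid <- grow_fibres(grid, s, growth_policy("uniform", iterations = 50L,
                                             cap_factor = 1.0, seed = 2))
  mesh <- fibre_meshes(grid, "outer", smooth_iters = 3L, decim_fraction = 1)[[1]]
  pr <- equivalent_radius_profile(mesh, alt, step = 1)
  rad <- pr$radius[!is.na(pr$radius)]
  expect_gt(max(rad) - min(rad), 0.6)   # oscillation spans most of the 1 um swing
})

test_that("erosion carves a consistent inner compartment", {
  # depth-0 erosion: inner = outer, MVF = 0 (g_target = 1)
  s20 <- make_fixture("bundle-20")
  g <- rasterize_capsules(s20, 0.1)
  g <- grow_fibres(g, s20, growth_policy("uniform", 1000L, cap_factor = 1.5, seed = 5))
  g0 <- erode_inner(g, s20, g_target = 1)
  vf0 <- volume_fractions(g0)
  expect_equal(vf0[["MVF"]], 0)
  expect_equal(vf0[["AVF"]], vf0[["FVF"]])

  # ideal cylinder of 10-voxel radius eroded by 3 voxels: inner radius ~ 7 voxels
  f <- fibre_skeleton(rbind(c(0, 0, -1), c(0, 0, 11)), c(1, 1), id = 1)
  s <- substrate(list(f), rbind(c(-1.5, -1.5, 0), c(1.5, 1.5, 10)))
  gc <- rasterize_capsules(s, 0.1)
  depth <- wmphantom:::cpp_depth(gc$owner, gc$dim)
  inner <- wmphantom:::cpp_make_inner(gc$owner, depth, 3L)
  mid <- gc$dim[3] %/% 2
  slab <- function(field) {
    arr <- array(field, dim = gc$dim)
    sum(arr[, , mid] > 0)
  }
  r_out <- sqrt(slab(gc$owner) / pi)
  r_in <- sqrt(slab(inner) / pi)
  expect_equal(r_out, 10, tolerance = 0.05)
  expect_equal(r_in, 7, tolerance = 0.08)

  # identity AVF + MVF + EVF = 1 exactly, inner subset of outer
  gi <- erode_inner(g, s20, g_target = 0.7)
  vf <- volume_fractions(gi)
  expect_identical(vf[["AVF"]] + vf[["MVF"]] + vf[["EVF"]], 1 - vf[["FVF"]] + vf[["AVF"]] + vf[["MVF"]])
  expect_equal(vf[["AVF"]] + vf[["MVF"]], vf[["FVF"]])
  expect_true(all(gi$owner[gi$inner > 0] == gi$inner[gi$inner > 0]))
  achieved_g <- g_ratio(vf[["MVF"]], vf[["FVF"]])
  expect_lt(abs(achieved_g - 0.7), 0.03)
})
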