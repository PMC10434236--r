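test_that("volume fractions match hand-counted ratios and their identities", {
  # empty grid
  s0 <- substrate(list(), rbind(c(0, 0, 0), c(2, 2, 2)))
  g0 <- rasterize_capsules(s0, 0.2)
  vf0 <- volume_fractions(g0, region = s0$box)
  expect_equal(unname(vf0), c(0, 0, 0, 1))

  # hand-built labelled toy grid: 1000 voxels, 300 owned of which 120 inner
  dim <- c(10L, 10L, 10L)
  owner <- integer(1000)
  owner[1:300] <- rep(1:3, each = 100)
  inner <- integer(1000)
  inner[c(1:40, 101:140, 201:240)] <- rep(1:3, each = 40)
  g <- wmphantom:::voxel_grid(owner, integer(1000), dim, 0.1, c(0, 0, 0), 3L,
                              inner = inner)
  vf <- volume_fractions(g, region = rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(vf[["FVF"]], 0.3)
  expect_equal(vf[["AVF"]], 0.12)
  expect_equal(vf[["MVF"]], 0.18)
  expect_equal(vf[["EVF"]], 0.7)
  expect_equal(vf[["AVF"]] + vf[["MVF"]], vf[["FVF"]])

  # fully owned grid with inner = outer
  g2 <- wmphantom:::voxel_grid(rep(1L, 1000), integer(1000), dim, 0.1,
                               c(0, 0, 0), 1L, inner = rep(1L, 1000))
  vf2 <- volume_fractions(g2, region = rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(unname(vf2), c(1, 0, 1, 0))
})

test_that("g_ratio implements the aggregate volume-fraction relation", {
  expect_equal(g_ratio(0, 50), 1)                  # no myelin
  expect_equal(g_ratio(30, 60), sqrt(0.5))
  expect_error(g_ratio(10, 0), "positive")
  expect_error(g_ratio(70, 60))
  # fractions and percentages agree
  expect_equal(g_ratio(0.35, 0.60), g_ratio(35, 60))
})

test_that("equivalent-radius profiles recover cylinder calibres", {
  # ideal cylinder radius 1: every profile value within 2%
  f <- fibre_skeleton(rbind(c(0, 0, -1), c(0, 0, 11)), c(1, 1), id = 1)
  s <- substrate(list(f), rbind(c(-1.5, -1.5, 0), c(1.5, 1.5, 10)))
  g <- rasterize_capsules(s, 0.05)
  m <- fibre_meshes(g, "outer", smooth_iters = 3L, decim_fraction = 1)[[1]]
  pr <- equivalent_radius_profile(m, f, step = 1)
  mid <- pr$radius[pr$arc_position > 1 & pr$arc_position < 11]
  expect_true(all(abs(mid - 1) < 0.02))

  # elliptic cylinder semi-axes 2 x 0.5: equivalent radius sqrt(ab) = 1
  fx <- make_fixture("elliptic-cylinder")
  me <- mask_to_mesh(fx$mask, fx$res, fx$origin)
  pre <- equivalent_radius_profile(me, fx$skeleton, step = 1)
  expect_true(all(abs(pre$radius[!is.na(pre$radius)] - 1) < 0.02))
})

test_that("profiles are invariant under rigid motion of mesh plus skeleton", {
  fx <- make_fixture("elliptic-cylinder")
  m <- mask_to_mesh(fx$mask, fx$res, fx$origin)
  pr0 <- equivalent_radius_profile(m, fx$skeleton, step = 2)
  th <- 0.83
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(0.4), -sin(0.4)), c(0, sin(0.4), cos(0.4)))
  shift <- c(3.2, -1.1, 7.9)
  m2 <- m
  m2$vertices <- sweep(m$vertices %*% t(Q), 2, -shift)
  sk2 <- fx$skeleton
  sk2$points <- sweep(sk2$points %*% t(Q), 2, -shift)
  pr1 <- equivalent_radius_profile(m2, sk2, step = 2)
  expect_equal(pr1$radius, pr0$radius, tolerance = 1e-6)
})

test_that("radii distribution distance: exact targets give ~0, hand values check out", {
  dist <- radius_distribution()
  set.seed(6)
  ideal <- sample_radii(dist, 4000)
  rd <- radii_distribution(ideal, dist)
  expect_lt(rd$wasserstein1, 0.05)
  expect_lt(rd$ks, 0.05)

  # three-fibre toy: means equal hand-computed values
  means <- c(0.6, 0.9, 1.4)
  rd3 <- radii_distribution(means, dist)
  expect_equal(rd3$mean_radii, means)
  expect_gt(rd3$wasserstein1, 0)
})

test_that("dispersion angle: parallel fibres give 0, a 10-degree cone gives 10", {
  mk <- function(dir, id) {
    dir <- dir / sqrt(sum(dir^2))
    fibre_skeleton(rbind(c(0, 0, 0), 10 * dir), c(0.5, 0.5), id = id)
  }
  par <- lapply(1:5, function(i) mk(c(0, 0, 1), i))
  expect_equal(as.numeric(dispersion_angle(par, c(0, 0, 1))), 0)

  th <- 10 * pi / 180
  cone <- lapply(1:12, function(i) {
    psi <- 2 * pi * i / 12
    mk(c(sin(th) * cos(psi), sin(th) * sin(psi), cos(th)), i)
  })
  expect_equal(as.numeric(dispersion_angle(cone, c(0, 0, 1))), 10, tolerance = 1e-9)

  zerolen <- list(fibre_skeleton(rbind(c(0, 0, 0), c(0, 0, 0) + 1e-15), c(1, 1), id = 1))
  expect_error(dispersion_angle(zerolen), "zero-length")
})
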