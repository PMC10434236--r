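test_that("radius sampling is seeded, truncated, and matches the quadrature mean", {
  dist <- radius_distribution(shape = 0.5, scale = 1.1, trunc = c(0.5, 4))
  r1 <- sample_radii(dist, 500, seed = 11)
  r2 <- sample_radii(dist, 500, seed = 11)
  expect_identical(r1, r2)

  d <- 2 * sample_radii(dist, 1e5, seed = 12)
  expect_gte(min(d), 0.5)
  expect_lte(max(d), 4)
  expect_lt(abs(mean(d) - truncated_gamma_mean(dist)) / truncated_gamma_mean(dist),
            0.01)

  # negligible-mass truncation must error
  expect_error(sample_radii(radius_distribution(trunc = c(30, 31)), 10),
               "negligible")
})

test_that("disk packing: single-disk density, empty input, and the overlap oracle", {
  one <- pack_disks_2d(10, 1)
  expect_equal(attr(one, "density"), pi / 100)
  expect_equal(nrow(one), 1)

  none <- pack_disks_2d(10, numeric(0))
  expect_equal(attr(none, "density"), 0)

  dist <- radius_distribution()
  r <- sample_radii(dist, 200, seed = 4)
  L <- sqrt(sum(pi * r^2) / 0.5)          # face sized for 50% density
  centres <- pack_disks_2d(L, r, target_density = 0.5, seed = 4)
  expect_equal(attr(centres, "density"), 0.5, tolerance = 1e-6)
  # O(n^2) oracle: pairwise separations and containment
  dd <- as.matrix(dist(centres))
  diag(dd) <- Inf
  expect_true(all(dd >= outer(r, r, "+") - 1e-9))
  expect_true(all(centres >= r - 1e-9 & centres <= L - r + 1e-9))
})

test_that("bundle initialisation realises dispersion targets", {
  s0 <- init_bundle(bundle_spec(L = 15, H = 15, density = 0.4, eta = 0, seed = 2))
  expect_equal(as.numeric(dispersion_angle(s0)), 0)
  expect_equal(overlap_count(s0)$count, 0)   # parallel disjoint cylinders

  s10 <- init_bundle(bundle_spec(L = 35, H = 35, density = 0.5, eta = 10, seed = 2))
  expect_gte(length(s10$fibres), 300)
  expect_gt(as.numeric(dispersion_angle(s10)), 9)
  expect_lt(as.numeric(dispersion_angle(s10)), 11)
})

test_that("the shrink rule caps the initial 2D density at 0.75 and records full-size radii", {
  s9 <- init_bundle(bundle_spec(L = 15, H = 15, density = 0.9, eta = 0, seed = 3))
  packed <- sum(pi * vapply(s9$fibres, function(f) f$radii[1], numeric(1))^2) / 15^2
  expect_lte(packed, 0.75 + 1e-9)
  full <- sum(pi * vapply(s9$fibres, function(f) f$target_radii[1], numeric(1))^2) / 15^2
  expect_equal(full, 0.9, tolerance = 0.02)
  expect_equal(s9$bundles$shrink, sqrt(0.75 / 0.9))
})

test_that("crossing construction is rigid and preserves per-bundle dispersion", {
  narrow <- radius_distribution(shape = 60, scale = 1 / 60, trunc = c(0.8, 1.2))
  bs <- bundle_spec(L = 8, H = 16, density = 0.3, eta = 5, dist = narrow, seed = 21)
  sx <- init_crossing(crossing_spec(bs, bs, theta = 90))
  ax1 <- unlist(sx$bundles[1, c("ax", "ay", "az")])
  ax2 <- unlist(sx$bundles[2, c("ax", "ay", "az")])
  ang <- acos(abs(sum(ax1 * ax2))) * 180 / pi
  expect_equal(ang, 90, tolerance = 1)

  for (b in 1:2) {
    d <- as.numeric(dispersion_angle(sx, bundle = b))
    expect_gt(d, 3.5); expect_lt(d, 6.5)     # eta = 5 preserved by rigid motion
  }

  # isometry: polyline lengths unchanged through the transform
  sx30 <- init_crossing(crossing_spec(bs, bs, theta = 30))
  plain <- init_bundle(bs)
  len <- function(f) sum(sqrt(rowSums((f$points[-1, , drop = FALSE] -
                                         f$points[-nrow(f$points), , drop = FALSE])^2)))
  l1 <- vapply(plain$fibres, len, numeric(1))
  l2 <- vapply(sx30$fibres[seq_along(l1)], len, numeric(1))
  expect_equal(l2, l1, tolerance = 1e-9)
})

test_that("crossing trim keeps exactly the fibres that meet the region and clips them to it", {
  s20 <- make_fixture("bundle-20")
  full <- trim_crossing(s20, region = s20$box)
  expect_equal(length(full$fibres), length(s20$fibres))

  sx <- make_fixture("crossing-60")
  cen <- colMeans(sx$box)
  half <- min(sx$box[2, ] - sx$box[1, ]) / 4
  region <- rbind(cen - half, cen + half)
  tr <- trim_crossing(sx, region)
  expect_gt(length(tr$fibres), 0)
  for (f in tr$fibres) {
    expect_true(all(sweep(f$points, 2, region[1, ]) >= -1e-6))
    expect_true(all(sweep(f$points, 2, region[2, ]) <= 1e-6))
    # re-terminated ends sit on the region boundary (within one capsule length)
    spacing <- max(2 * f$radii)
    end_dists <- vapply(c(1, nrow(f$points)), function(i) {
      min(abs(c(f$points[i, ] - region[1, ], f$points[i, ] - region[2, ])))
    }, numeric(1))
    expect_lt(end_dists[1], spacing + 1e-6)
    expect_lt(end_dists[2], spacing + 1e-6)
  }
  expect_error(trim_crossing(sx, region = rbind(c(1e4, 1e4, 1e4), c(1e4 + 1, 1e4 + 1, 1e4 + 1))),
               "no fibres")
})
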