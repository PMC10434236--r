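test_that("broad-phase candidate pairs form a superset of the O(n^2) overlap oracle", {
  s <- random_capsule_substrate(500, box_side = 14, seed = 8)
  cand <- candidate_pairs(s)
  oracle <- oracle_overlap_pairs(s)
  expect_gt(nrow(oracle), 10)    # the fixture must actually contain overlaps
  cand_keys <- paste(cand[, 1], cand[, 2])
  oracle_keys <- paste(oracle[, 1], oracle[, 2])
  expect_true(all(oracle_keys %in% cand_keys))
  # no same-fibre pairs, each unordered pair once
  arr <- wmphantom:::substrate_arrays(s)
  expect_true(all(arr$capF[cand[, 1] + 1L] != arr$capF[cand[, 2] + 1L]))
  expect_false(anyDuplicated(cand_keys) > 0)
})

test_that("far-apart capsules are never paired", {
  f1 <- fibre_skeleton(rbind(c(0, 0, 0), c(1, 0, 0)), c(0.5, 0.5), id = 1)
  f2 <- fibre_skeleton(rbind(c(40, 40, 40), c(41, 40, 40)), c(0.5, 0.5), id = 2)
  s <- substrate(list(f1, f2), rbind(rep(-1, 3), rep(45, 3)))
  expect_equal(nrow(candidate_pairs(s)), 0)
})

test_that("overlap_count agrees with brute force and flags coincident capsules", {
  s <- random_capsule_substrate(120, box_side = 8, seed = 5)
  expect_equal(overlap_count(s)$count, nrow(oracle_overlap_pairs(s)))

  f1 <- fibre_skeleton(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, 1), id = 1)
  s2 <- substrate(list(f1, fibre_skeleton(f1$points, f1$radii, id = 2)),
                  rbind(rep(-2, 3), rep(3, 3)))
  oc <- overlap_count(s2)
  expect_equal(oc$count, 1)
  expect_equal(oc$max_D, 1)
})

test_that("an overlap-free substrate is a fixed point of the overlap phase", {
  s <- make_fixture("bundle-20")
  out <- optimize_substrate(s)
  expect_equal(overlap_count(out)$count, 0)
  for (i in seq_along(s$fibres)) {
    m <- nrow(s$fibres[[i]]$points)
    expect_equal(out$fibres[[i]]$points[c(1, m), ], s$fibres[[i]]$points[c(1, m), ])
  }
})

test_that("two unit-radius fibres forced to 1 um axis separation end >= 2 um apart", {
  # fibre 1 straight at x = 0; fibre 2 anchored 2.4 um away at the faces but
  # bowed to 1 um separation mid-span.  With radii held at 1, the optimizer
  # must push every closest approach back to >= 2 um.
  z <- seq(0, 12, length.out = 9)
  f1 <- fibre_skeleton(cbind(0, 0, z), rep(1, 9), id = 1L)
  bow <- 2.4 - 1.4 * sin(pi * z / 12)          # 2.4 at ends, 1.0 at midspan
  f2 <- fibre_skeleton(cbind(bow, 0, z), rep(1, 9), id = 2L)
  s <- substrate(list(f1, f2), rbind(c(-4, -4, 0), c(7, 4, 12)))
  attr(s, "reference") <- s
  expect_gt(overlap_count(s)$count, 0)
  out <- optimize_substrate(s, schedule = optimizer_schedule(radius_bounds = c(1, 1)))
  expect_equal(overlap_count(out)$count, 0)
  arr <- wmphantom:::substrate_arrays(out)
  expect_equal(arr$R, rep(1, 18))              # radii were held fixed
  for (i in 1:8) {
    for (j in 1:8) {
      ai <- arr$capA[i] + 1L; aj <- arr$capA[8 + j] + 1L
      cl <- segment_closest_params(arr$P[ai, ], arr$P[ai + 1, ],
                                   arr$P[aj, ], arr$P[aj + 1, ])
      expect_gte(cl$distance, 2 - 1e-6)
    }
  }
})

test_that("the toy crossing is disentangled with bounded orientation drift", {
  sx <- make_fixture("crossing-60")
  expect_gt(overlap_count(sx)$count, 0)
  out <- optimize_substrate(sx)
  expect_equal(overlap_count(out)$count, 0)
  for (b in 1:2) {
    drift <- abs(as.numeric(dispersion_angle(out, bundle = b)) -
                   as.numeric(dispersion_angle(sx, bundle = b)))
    expect_lt(drift, 5)
  }
  # iteration log records both phases and ends overlap-free
  log <- attr(out, "log")
  expect_true(all(c("overlap_count", "overlap", "curvature") %in% names(log)))
  expect_equal(log$overlap_count[nrow(log)], 0)
})

test_that("optimization is deterministic and the failure path reports residuals", {
  s4 <- make_fixture("four-fibre-toy")
  a <- optimize_substrate(s4)
  b <- optimize_substrate(s4)
  expect_identical(a$fibres, b$fibres)

  # an impossible budget must error with the residual overlap report
  expect_error(
    optimize_substrate(s4, schedule = optimizer_schedule(max_blocks = 1L,
                                                         block_overlap = 1L,
                                                         block_polish = 0L)),
    "overlapping capsule pairs remain")
})
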