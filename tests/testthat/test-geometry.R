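test_that("closest approach matches worked examples and tie-breaks", {
  cl <- segment_closest_params(c(0, 0, 0), c(2, 0, 0), c(1, 1, -1), c(1, 1, 1))
  expect_equal(cl$t_p, 0.5)
  expect_equal(cl$t_q, 0.5)
  expect_equal(cl$distance, 1)

  # identical segments: zero distance, deterministic midrange tie-break t_p == t_q
  cl2 <- segment_closest_params(c(0, 0, 0), c(1, 2, 3), c(0, 0, 0), c(1, 2, 3))
  expect_equal(cl2$distance, 0)
  expect_equal(cl2$t_p, cl2$t_q)

  # degenerate point segments
  cl3 <- segment_closest_params(c(0, 0, 0), c(0, 0, 0), c(3, 4, 0), c(3, 4, 0))
  expect_equal(cl3$t_p, 0)
  expect_equal(cl3$t_q, 0)
  expect_equal(cl3$distance, 5)
})

test_that("closed-form closest distance agrees with the brute-force grid oracle", {
  set.seed(101)
  n_pairs <- 250   # a further 1000-pair sweep runs in the acceptance suite
  for (k in seq_len(n_pairs)) {
    p0 <- runif(3, -2, 2); p1 <- runif(3, -2, 2)
    q0 <- runif(3, -2, 2); q1 <- runif(3, -2, 2)
    d_closed <- segment_closest_params(p0, p1, q0, q1)$distance
    d_oracle <- oracle_closest_distance(p0, p1, q0, q1)
    expect_lte(d_closed, d_oracle + 1e-9)           # closed form is the true min
    expect_lt(abs(d_closed - d_oracle), 0.02)       # oracle grid resolution
  }
})

test_that("overlap cost reproduces the hand-evaluated configurations", {
  # coincident unit-length capsules, all radii 1: every factor is 1
  a <- capsule(c(0, 0, 0), c(1, 0, 0), 1)
  expect_equal(as.numeric(capsule_overlap_cost(a, a)), 1)
  expect_equal(attr(capsule_overlap_cost(a, a), "D"), 1)

  # closest spheres exactly touching: cost 0
  b <- capsule(c(0, 2, 0), c(1, 2, 0), 1)
  expect_equal(as.numeric(capsule_overlap_cost(a, b)), 0)

  # parallel unit capsules 1 um apart, radii 1: D = 0.5, cost = 0.25
  c2 <- capsule(c(0, 1, 0), c(1, 1, 0), 1)
  got <- capsule_overlap_cost(a, c2)
  expect_equal(attr(got, "D"), 0.5)
  expect_equal(as.numeric(got), 0.25)
})

test_that("overlap cost is symmetric, zero iff spheres disjoint, continuous at D = 0", {
  set.seed(7)
  for (k in 1:200) {
    a <- capsule(runif(3, 0, 4), runif(3, 0, 4), runif(1, 0.2, 1.5), runif(1, 0.2, 1.5))
    b <- capsule(runif(3, 0, 4), runif(3, 0, 4), runif(1, 0.2, 1.5), runif(1, 0.2, 1.5))
    cab <- capsule_overlap_cost(a, b)
    cba <- capsule_overlap_cost(b, a)
    expect_equal(as.numeric(cab), as.numeric(cba), tolerance = 1e-12)
    cl <- segment_closest_params(a$p0, a$p1, b$p0, b$p1, a$r0, a$r1, b$r0, b$r1)
    expect_equal(as.numeric(cab) > 0, cl$D > 0)
  }
  # continuity across the contact boundary: cost ~ D^2 -> vanishes smoothly
  base <- capsule(c(0, 0, 0), c(1, 0, 0), 1)
  eps <- 1e-5
  near <- capsule(c(0, 2 - eps, 0), c(1, 2 - eps, 0), 1)
  expect_lt(as.numeric(capsule_overlap_cost(base, near)), 1e-8)
})

test_that("pairwise analytic gradients match central finite differences", {
  set.seed(42)
  h <- 1e-6
  checked <- 0
  for (rep in 1:12) {
    P <- matrix(rnorm(12), 4, 3)
    R <- runif(4, 0.5, 1.5)
    g <- wmphantom:::cpp_capsule_pair_cost(P, R, grad = TRUE)
    if (g$cost <= 1e-6) next
    checked <- checked + 1
    for (i in 1:4) {
      for (k in 1:3) {
        Pp <- P; Pp[i, k] <- Pp[i, k] + h
        Pm <- P; Pm[i, k] <- Pm[i, k] - h
        fd <- (wmphantom:::cpp_capsule_pair_cost(Pp, R)$cost -
                 wmphantom:::cpp_capsule_pair_cost(Pm, R)$cost) / (2 * h)
        expect_lt(abs(fd - g$grad_points[i, k]) / max(abs(fd), 1e-6), 1e-5)
      }
      Rp <- R; Rp[i] <- Rp[i] + h
      Rm <- R; Rm[i] <- Rm[i] - h
      fd <- (wmphantom:::cpp_capsule_pair_cost(P, Rp)$cost -
               wmphantom:::cpp_capsule_pair_cost(P, Rm)$cost) / (2 * h)
      expect_lt(abs(fd - g$grad_radii[i]) / max(abs(fd), 1e-6), 1e-5)
    }
  }
  expect_gte(checked, 5)
})

test_that("regularizer costs vanish at the initial straight state and grow as intended", {
  pts <- cbind(0, 0, seq(0, 10, length.out = 6))
  f <- fibre_skeleton(pts, rep(1, 6))
  rc <- regularizer_costs(f, f, axis = c(0, 0, 1), axis_point = c(0, 0, 0))
  expect_equal(rc[["curvature"]], 0)
  expect_equal(rc[["length"]], 0)
  expect_equal(rc[["radii_change"]], 0)

  # lateral midpoint displacement: curvature and length strictly positive
  f2 <- f
  f2$points[3, 1] <- 0.8
  rc2 <- regularizer_costs(f2, f)
  expect_gt(rc2[["curvature"]], 0)
  expect_gt(rc2[["length"]], 0)

  # uniform radii rescale: radii term positive, curvature untouched
  f3 <- f
  f3$radii <- 1.1 * f3$radii
  rc3 <- regularizer_costs(f3, f)
  expect_equal(rc3[["radii_change"]], sum((0.1)^2 * rep(1, 6)))
  expect_equal(rc3[["curvature"]], 0)
})

test_that("substrate cost: disjoint -> zero overlap; rigid translation invariant; gradient matches FD", {
  s20 <- make_fixture("bundle-20")
  st <- total_cost_and_gradient(s20, cost_weights())
  expect_equal(st$terms[["overlap"]], 0)

  s4 <- make_fixture("four-fibre-toy")
  w <- cost_weights()
  base <- total_cost_and_gradient(s4, w)
  expect_gt(base$terms[["overlap"]], 0)

  # rigid translation leaves the overlap term unchanged
  s4t <- s4
  for (i in seq_along(s4t$fibres))
    s4t$fibres[[i]]$points <- sweep(s4t$fibres[[i]]$points, 2, -c(1.3, -0.7, 2.1))
  shifted <- total_cost_and_gradient(s4t, w, reference = s4t)
  expect_equal(shifted$terms[["overlap"]], base$terms[["overlap"]], tolerance = 1e-9)

  # full-substrate analytic gradient vs central differences
  arr <- wmphantom:::substrate_arrays(s4)
  h <- 1e-6
  set.seed(33)
  probe <- sample(which(!arr$fixed), 6)
  perturb_cost <- function(i, k, delta, radii = FALSE) {
    s2 <- s4
    fi <- arr$point_fib[i]
    li <- i - arr$off[fi]
    if (radii) s2$fibres[[fi]]$radii[li] <- s2$fibres[[fi]]$radii[li] + delta
    else s2$fibres[[fi]]$points[li, k] <- s2$fibres[[fi]]$points[li, k] + delta
    total_cost_and_gradient(s2, w, reference = s4)$cost
  }
  for (i in probe) {
    for (k in 1:3) {
      fd <- (perturb_cost(i, k, h) - perturb_cost(i, k, -h)) / (2 * h)
      expect_lt(abs(fd - base$grad_points[i, k]) / max(abs(fd), 1e-6), 1e-5)
    }
    fd <- (perturb_cost(i, 0, h, radii = TRUE) -
             perturb_cost(i, 0, -h, radii = TRUE)) / (2 * h)
    expect_lt(abs(fd - base$grad_radii[i]) / max(abs(fd), 1e-6), 1e-5)
  }
})
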