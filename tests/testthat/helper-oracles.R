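# Independent oracles used across the suite.

# Brute-force minimizer of the squared segment-segment distance over a
# (ta, tb) grid, refined once around the best cell.  Resolution after
# refinement ~ (2/n)^2, far below the comparison tolerances.
oracle_closest_distance <- function(p0, p1, q0, q1, n = 201L) {
  eval_grid <- function(lo_a, hi_a, lo_b, hi_b) {
    ta <- seq(lo_a, hi_a, length.out = n)
    tb <- seq(lo_b, hi_b, length.out = n)
    d1 <- p1 - p0; d2 <- q1 - q0
    best <- Inf; best_ab <- c(0, 0)
    # vectorised over tb for each ta
    for (a in ta) {
      pa <- p0 + a * d1
      dx <- outer(tb, d2[1]) + q0[1] - pa[1]
      dy <- outer(tb, d2[2]) + q0[2] - pa[2]
      dz <- outer(tb, d2[3]) + q0[3] - pa[3]
      g <- dx^2 + dy^2 + dz^2
      i <- which.min(g)
      if (g[i] < best) { best <- g[i]; best_ab <- c(a, tb[i]) }
    }
    list(d2 = best, ab = best_ab)
  }
  c1 <- eval_grid(0, 1, 0, 1)
  h <- 1 / (n - 1)
  lo <- pmax(c1$ab - h, 0); hi <- pmin(c1$ab + h, 1)
  c2 <- eval_grid(lo[1], hi[1], lo[2], hi[2])
  sqrt(min(c1$d2, c2$d2))
}

# O(n^2) overlapping-pair oracle on a flattened substrate (cross-fibre pairs
# with positive overlap depth).
oracle_overlap_pairs <- function(s) {
  arr <- wmphantom:::substrate_arrays(s)
  nc <- length(arr$capA)
  pairs <- list()
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      if (arr$capF[i] == arr$capF[j]) next
      ai <- arr$capA[i] + 1L; aj <- arr$capA[j] + 1L
      cl <- segment_closest_params(arr$P[ai, ], arr$P[ai + 1, ],
                                   arr$P[aj, ], arr$P[aj + 1, ],
                                   arr$R[ai], arr$R[ai + 1],
                                   arr$R[aj], arr$R[aj + 1])
      if (cl$D > 0) pairs[[length(pairs) + 1L]] <- c(i - 1L, j - 1L)
    }
  }
  if (length(pairs) == 0) matrix(integer(0), 0, 2) else do.call(rbind, pairs)
}

# Random multi-fibre substrate of short 2-point fibres (i.e. single capsules)
# for broad-phase tests.
random_capsule_substrate <- function(n, box_side = 12, seed = 1) {
  set.seed(seed)
  fib <- lapply(seq_len(n), function(i) {
    a <- runif(3, 0, box_side)
    d <- rnorm(3); d <- d / sqrt(sum(d^2)) * runif(1, 0.5, 2)
    r <- runif(2, 0.2, 0.8)
    fibre_skeleton(rbind(a, a + d), r, id = i)
  })
  s <- substrate(fib, rbind(rep(0, 3), rep(box_side, 3)))
  attr(s, "reference") <- s
  s
}

# Watertightness via edge bookkeeping, independent of validate_mesh.
edges_closed <- function(F) {
  ed <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(ed[, 1], ed[, 2])
  rkey <- paste(ed[, 2], ed[, 1])
  !anyDuplicated(key) && all(key %in% rkey)
}
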