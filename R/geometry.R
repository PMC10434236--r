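#' Capsule (swept sphere) collision primitive
#'
#' A capsule is the volume swept by a sphere whose centre moves from `p0` to
#' `p1` while its radius interpolates linearly from `r0` to `r1`.  It is the
#' unit of collision geometry: every pair of consecutive control points along
#' a fibre skeleton forms one capsule.  Degenerate capsules with `p0 == p1`
#' (plain spheres) are allowed and evaluate normally.
#'
#' @param p0,p1 numeric 3-vectors, the endpoint centres (um).
#' @param r0,r1 positive radii at the two endpoints (um).
#' @return An object of class `capsule`.
#' @examples
#' capsule(c(0, 0, 0), c(2, 0, 0), 1, 1)
#' @export
capsule <- function(p0, p1, r0, r1 = r0) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  stopifnot(length(p0) == 3, length(p1) == 3, all(is.finite(c(p0, p1))))
  if (r0 <= 0 || r1 <= 0) stop("capsule radii must be positive")
  structure(list(p0 = p0, p1 = p1, r0 = as.numeric(r0), r1 = as.numeric(r1)),
            class = "capsule")
}

#' @export
print.capsule <- function(x, ...) {
  cat(sprintf("<capsule> [%.3g, %.3g, %.3g] -> [%.3g, %.3g, %.3g], r %.3g -> %.3g um\n",
              x$p0[1], x$p0[2], x$p0[3], x$p1[1], x$p1[2], x$p1[3], x$r0, x$r1))
  invisible(x)
}

#' Fibre skeleton: a chain of capsules
#'
#' A fibre is parameterised by an ordered list of 3D control points with one
#' radius per point; consecutive point pairs form capsules, and adjacent
#' capsules share their common control point and radius.  `target_radii`
#' records the full-size radii the fibre should reach after radial growth
#' (they differ from `radii` when the initial packing had to shrink radii).
#'
#' @param points numeric matrix (m x 3) of control points (um), m >= 2.
#' @param radii positive numeric vector of length m (um).
#' @param id integer fibre identifier.
#' @param bundle integer bundle identifier.
#' @param target_radii full-size radii (um); defaults to `radii`.
#' @return An object of class `fibre_skeleton`.
#' @export
fibre_skeleton <- function(points, radii, id = 1L, bundle = 1L,
                           target_radii = radii) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (nrow(points) < 2 || ncol(points) != 3) stop("need >= 2 control points (m x 3)")
  radii <- as.numeric(radii)
  if (length(radii) != nrow(points)) stop("radii must match control points")
  if (any(radii <= 0)) stop("radii must be positive")
  if (length(target_radii) != length(radii)) stop("target_radii must match radii")
  structure(list(id = as.integer(id), bundle = as.integer(bundle),
                 points = points, radii = radii,
                 target_radii = as.numeric(target_radii)),
            class = "fibre_skeleton")
}

#' @export
print.fibre_skeleton <- function(x, ...) {
  cat(sprintf("<fibre_skeleton> id %d, bundle %d, %d control points, mean radius %.3g um\n",
              x$id, x$bundle, nrow(x$points), mean(x$radii)))
  invisible(x)
}

#' Number of capsules of a fibre
#' @param f a `fibre_skeleton`.
#' @return integer.
#' @export
n_capsules <- function(f) nrow(f$points) - 1L

#' Closest approach between two capsule axes
#'
#' Finds the normalised parameters `(t_p, t_q)` in the unit square that
#' minimise the squared distance between the two segments, with the standard
#' closed-form solution and clamped re-projection at the boundary.  For
#' parallel segments the midrange of the overlap interval is used, so
#' coincident segments deterministically return `t_p == t_q`.  Degenerate
#' zero-length segments are treated as points (parameter fixed at 0).
#'
#' @param p0,p1 endpoints of the first segment (um).
#' @param q0,q1 endpoints of the second segment (um).
#' @param r_p0,r_p1,r_q0,r_q1 optional endpoint radii used to interpolate
#'   `r_p`, `r_q` and the overlap depth `D` at the closest approach.
#' @return A list of class `closest_approach` with elements `t_p`, `t_q`,
#'   `c1`, `c2` (closest centres, um), `r_p`, `r_q` (interpolated radii),
#'   `distance` and the dimensionless overlap depth `D = 1 - |c1-c2|/(r_p+r_q)`.
#' @examples
#' segment_closest_params(c(0,0,0), c(2,0,0), c(1,1,-1), c(1,1,1))
#' @export
segment_closest_params <- function(p0, p1, q0, q1,
                                   r_p0 = 1, r_p1 = r_p0, r_q0 = 1, r_q1 = r_q0) {
  cl <- cpp_seg_closest(as.numeric(p0), as.numeric(p1),
                        as.numeric(q0), as.numeric(q1))
  r_p <- (1 - cl$t_p) * r_p0 + cl$t_p * r_p1
  r_q <- (1 - cl$t_q) * r_q0 + cl$t_q * r_q1
  d <- sqrt(sum((cl$c1 - cl$c2)^2))
  structure(list(t_p = cl$t_p, t_q = cl$t_q, c1 = cl$c1, c2 = cl$c2,
                 r_p = r_p, r_q = r_q, distance = d,
                 D = 1 - d / (r_p + r_q), parallel = cl$parallel),
            class = "closest_approach")
}

#' Pairwise capsule overlap cost
#'
#' The overlap penalty between two capsules is built from the interpenetration
#' of the two closest spheres centred on the capsule axes: with overlap depth
#' `D = 1 - |c1 - c2| / (r_p + r_q)` evaluated at the closest approach, the
#' cost is `D^2 * |p1-p0| * |q1-q0| * r_p * r_q` when `D >= 0` and exactly 0
#' otherwise.  The cost is symmetric in its two arguments and continuous in
#' all eight capsule parameters (it vanishes quadratically at `D = 0`).
#'
#' @param a,b objects of class `capsule`.
#' @return Non-negative scalar cost with attribute `D` (overlap depth).
#' @examples
#' a <- capsule(c(0,0,0), c(1,0,0), 1)
#' b <- capsule(c(0,1,0), c(1,1,0), 1)
#' capsule_overlap_cost(a, b)   # D = 0.5, cost 0.25
#' @export
capsule_overlap_cost <- function(a, b) {
  stopifnot(inherits(a, "capsule"), inherits(b, "capsule"))
  P <- rbind(a$p0, a$p1, b$p0, b$p1)
  out <- cpp_capsule_pair_cost(P, c(a$r0, a$r1, b$r0, b$r1), grad = FALSE)
  structure(out$cost, D = out$D)
}

#' Cost weights for the joint fibre optimization
#'
#' Non-negative weights of the five cost terms, ordered by their priority of
#' penalisation: fibre overlap, curvature, length increase, radii change and
#' compactness.  During the overlap-removal phase the overlap weight must
#' strictly dominate all others; the defaults satisfy this by an order of
#' magnitude per rank.
#'
#' @param overlap,curvature,length,radii_change,compactness non-negative
#'   weights.  Units are unnormalised (um-based); the weights absorb scale.
#' @return An object of class `cost_weights`.
#' @export
cost_weights <- function(overlap = 1, curvature = 0.1, length = 0.05,
                         radii_change = 0.02, compactness = 0.005) {
  w <- c(overlap = overlap, curvature = curvature, length = length,
         radii_change = radii_change, compactness = compactness)
  if (any(w < 0)) stop("cost weights must be non-negative")
  structure(as.list(w), class = "cost_weights")
}

#' Regularizer costs of one fibre
#'
#' Four smooth penalties keep fibres coherent while overlaps are removed.
#' Each is zero for a straight fibre at its initial length with unchanged
#' radii (compactness, which measures the bundle arrangement rather than the
#' deformation, is reported relative to its own definition):
#' \describe{
#'   \item{curvature}{sum of squared discrete second differences
#'     `sum ||x_{i-1} - 2 x_i + x_{i+1}||^2`.}
#'   \item{length}{squared positive part of the polyline length excess over
#'     the reference length.}
#'   \item{radii_change}{`sum (r_i - r_i^target)^2` against the fibre's
#'     full-size target radii.}
#'   \item{compactness}{squared distance of the fibre centroid to the bundle
#'     central axis (line through `axis_point` with direction `axis`).}
#' }
#'
#' @param f a `fibre_skeleton` (current state).
#' @param reference the fibre's initial straight configuration.
#' @param axis unit 3-vector, the bundle main orientation.
#' @param axis_point a point on the bundle central axis (um).
#' @return Named numeric vector `(curvature, length, radii_change, compactness)`.
#' @export
regularizer_costs <- function(f, reference = f, axis = c(0, 0, 1),
                              axis_point = c(0, 0, 0)) {
  if (nrow(f$points) != nrow(reference$points))
    stop("fibre and reference have different numbers of control points")
  P <- f$points
  m <- nrow(P)
  curv <- if (m >= 3) {
    d2 <- P[1:(m - 2), , drop = FALSE] - 2 * P[2:(m - 1), , drop = FALSE] +
      P[3:m, , drop = FALSE]
    sum(d2^2)
  } else 0
  len <- function(X) sum(sqrt(rowSums((X[-1, , drop = FALSE] -
                                         X[-nrow(X), , drop = FALSE])^2)))
  dl <- len(P) - len(reference$points)
  length_cost <- if (dl > 0) dl^2 else 0
  radii_cost <- sum((f$radii - f$target_radii)^2)
  axis <- axis / sqrt(sum(axis^2))
  cen <- colMeans(P)
  v <- cen - axis_point
  perp <- v - sum(v * axis) * axis
  c(curvature = curv, length = length_cost, radii_change = radii_cost,
    compactness = sum(perp^2))
}

# ---- flattened substrate views -------------------------------------------

# Flatten a substrate into the arrays the C++ kernels consume: stacked
# control points/radii, capsule index tables and per-fibre ranges (0-based
# for C++).
substrate_arrays <- function(s) {
  npts <- vapply(s$fibres, function(f) nrow(f$points), integer(1))
  off <- cumsum(c(0L, npts[-length(npts)]))
  P <- do.call(rbind, lapply(s$fibres, `[[`, "points"))
  R <- unlist(lapply(s$fibres, `[[`, "radii"), use.names = FALSE)
  Rt <- unlist(lapply(s$fibres, `[[`, "target_radii"), use.names = FALSE)
  capA <- integer(0); capF <- integer(0)
  fibCapLo <- integer(length(s$fibres)); fibCapHi <- integer(length(s$fibres))
  nc <- 0L
  for (i in seq_along(s$fibres)) {
    m <- npts[i]
    capA <- c(capA, off[i] + 0:(m - 2L))
    capF <- c(capF, rep(i - 1L, m - 1L))
    fibCapLo[i] <- nc
    nc <- nc + m - 1L
    fibCapHi[i] <- nc - 1L
  }
  fixed <- rep(FALSE, sum(npts))
  fixed[off + 1L] <- TRUE                       # first point of each fibre
  fixed[off + npts] <- TRUE                     # last point of each fibre
  list(P = P, R = R, Rt = Rt, npts = npts, off = off,
       capA = as.integer(capA), capF = as.integer(capF),
       fibCapLo = fibCapLo, fibCapHi = fibCapHi, fixed = fixed,
       point_fib = rep(seq_along(s$fibres), npts))
}

# Write flattened points/radii back into the fibre list.
substrate_from_arrays <- function(s, arr, P, R) {
  for (i in seq_along(s$fibres)) {
    idx <- (arr$off[i] + 1L):(arr$off[i] + arr$npts[i])
    s$fibres[[i]]$points <- P[idx, , drop = FALSE]
    s$fibres[[i]]$radii <- R[idx]
  }
  s
}

#' Total cost and analytic gradient of a substrate configuration
#'
#' Sums the pairwise capsule overlap cost over the candidate pairs (all
#' cross-fibre pairs found by the fixed-radius-cell broad phase unless an
#' explicit pair set is supplied) plus the four weighted regularizers, and
#' returns the analytic gradient with respect to every control point and
#' radius.  Gradient entries of the fixed fibre endpoints (the points pinned
#' to the cuboid faces) are zeroed.
#'
#' @param s a `substrate`.
#' @param weights a [cost_weights()] object.
#' @param pairs optional integer matrix of 0-based candidate capsule pairs
#'   (a superset of all overlapping cross-fibre pairs).
#' @param reference optional substrate holding the initial configuration used
#'   by the length regularizer; defaults to the reference stored at
#'   initialisation, or `s` itself.
#' @return List with `cost`, per-term breakdown `terms`, `grad_points`
#'   (N x 3), `grad_radii` (length N), `overlap_count` and `max_D`.
#' @export
total_cost_and_gradient <- function(s, weights = cost_weights(), pairs = NULL,
                                    reference = NULL) {
  stopifnot(inherits(s, "substrate"))
  arr <- substrate_arrays(s)
  ov <- cpp_overlap_total(arr$P, arr$R, arr$capA, arr$capF, pairs, TRUE)
  gP <- ov$grad_points * weights$overlap
  gR <- ov$grad_radii * weights$overlap
  if (is.null(reference)) reference <- attr(s, "reference") %||% s
  terms <- c(overlap = ov$cost, curvature = 0, length = 0,
             radii_change = 0, compactness = 0)
  reg_active <- (weights$curvature > 0 || weights$length > 0 ||
                   weights$radii_change > 0 || weights$compactness > 0)
  for (i in if (reg_active) seq_along(s$fibres) else integer(0)) {
    f <- s$fibres[[i]]
    fr <- reference$fibres[[i]]
    b <- s$bundles[s$bundles$id == f$bundle, ]
    axis <- c(b$ax, b$ay, b$az)
    axis_point <- c(b$cx, b$cy, b$cz)
    rc <- regularizer_costs(f, fr, axis, axis_point)
    terms[2:5] <- terms[2:5] + rc
    idx <- (arr$off[i] + 1L):(arr$off[i] + arr$npts[i])
    g <- fibre_regularizer_grad(f, fr, axis, axis_point)
    gP[idx, ] <- gP[idx, ] +
      weights$curvature * g$curvature +
      weights$length * g$length +
      weights$compactness * g$compactness
    gR[idx] <- gR[idx] + weights$radii_change * g$radii
  }
  gP[arr$fixed, ] <- 0
  cost <- weights$overlap * terms[["overlap"]] +
    weights$curvature * terms[["curvature"]] +
    weights$length * terms[["length"]] +
    weights$radii_change * terms[["radii_change"]] +
    weights$compactness * terms[["compactness"]]
  list(cost = cost, terms = terms, grad_points = gP, grad_radii = gR,
       overlap_count = ov$overlap_count, max_D = ov$max_D)
}

# Analytic gradients of the four regularizers for one fibre.
fibre_regularizer_grad <- function(f, reference, axis, axis_point) {
  P <- f$points
  m <- nrow(P)
  gc <- matrix(0, m, 3)
  if (m >= 3) {
    d2 <- P[1:(m - 2), , drop = FALSE] - 2 * P[2:(m - 1), , drop = FALSE] +
      P[3:m, , drop = FALSE]
    # d/dx of sum ||d2_i||^2: stencil (1, -2, 1)
    gc[1:(m - 2), ] <- gc[1:(m - 2), ] + 2 * d2
    gc[2:(m - 1), ] <- gc[2:(m - 1), ] - 4 * d2
    gc[3:m, ] <- gc[3:m, ] + 2 * d2
  }
  seg <- P[-1, , drop = FALSE] - P[-m, , drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  lens[lens < 1e-12] <- 1e-12
  unit <- seg / lens
  ref_len <- sum(sqrt(rowSums((reference$points[-1, , drop = FALSE] -
                                 reference$points[-m, , drop = FALSE])^2)))
  dl <- sum(lens) - ref_len
  gl <- matrix(0, m, 3)
  if (dl > 0) {
    # d(len)/dx_i = unit_{i} - unit_{i-1}; d(cost) = 2*dl*d(len)
    gl[-m, ] <- gl[-m, ] - unit
    gl[-1, ] <- gl[-1, ] + unit
    gl <- 2 * dl * gl
  }
  gr <- 2 * (f$radii - f$target_radii)
  axis <- axis / sqrt(sum(axis^2))
  cen <- colMeans(P)
  v <- cen - axis_point
  perp <- v - sum(v * axis) * axis
  # d/dx_i of ||perp(centroid)||^2 = (2/m) * perp
  gk <- matrix(rep(2 * perp / m, each = m), m, 3)
  list(curvature = gc, length = gl, radii = gr, compactness = gk)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
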