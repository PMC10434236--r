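#' Gamma radius distribution with diameter truncation
#'
#' Fibre outer diameters are drawn from a gamma distribution (shape `kappa`,
#' scale `theta`) and rejected outside the truncation bounds, reproducing the
#' long-tailed axon calibre distributions reported by histology.  Defaults
#' follow the white-matter reference configuration: diameters from
#' Gamma(shape 0.5, scale 1.1) truncated to 0.5--4 um.
#'
#' @param shape,scale gamma shape and scale (the distribution is sampled on
#'   diameters, in um).
#' @param trunc length-2 numeric, lower/upper diameter truncation (um).
#' @param shrink optional global shrink factor in (0, 1] applied to sampled
#'   radii (used by the initial packing when the target density exceeds the
#'   2D packing ceiling).
#' @return Object of class `radius_distribution`.
#' @export
radius_distribution <- function(shape = 0.5, scale = 1.1, trunc = c(0.5, 4),
                                shrink = 1) {
  if (shape <= 0 || scale <= 0) stop("gamma shape and scale must be positive")
  if (length(trunc) != 2 || trunc[1] >= trunc[2]) stop("invalid truncation bounds")
  if (shrink <= 0 || shrink > 1) stop("shrink factor must be in (0, 1]")
  structure(list(shape = shape, scale = scale, trunc = as.numeric(trunc),
                 shrink = shrink),
            class = "radius_distribution")
}

#' Mean of the truncated diameter distribution (by quadrature)
#' @param dist a [radius_distribution()].
#' @return Mean truncated diameter (um).
#' @export
truncated_gamma_mean <- function(dist) {
  Z <- pgamma(dist$trunc[2], dist$shape, scale = dist$scale) -
    pgamma(dist$trunc[1], dist$shape, scale = dist$scale)
  integrate(function(x) x * dgamma(x, dist$shape, scale = dist$scale),
            dist$trunc[1], dist$trunc[2])$value / Z
}

#' Sample fibre radii from a truncated gamma distribution
#'
#' Draws i.i.d. diameters from the gamma distribution, rejects draws outside
#' the truncation bounds, and returns radii (half-diameters) multiplied by
#' the distribution's shrink factor.  Reproducible under a fixed seed.
#'
#' @param dist a [radius_distribution()].
#' @param n number of radii (>= 1).
#' @param seed optional integer seed.
#' @return Numeric vector of n radii (um).
#' @export
sample_radii <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "radius_distribution"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  mass <- pgamma(dist$trunc[2], dist$shape, scale = dist$scale) -
    pgamma(dist$trunc[1], dist$shape, scale = dist$scale)
  if (mass < 1e-4)
    stop(sprintf("truncation bounds [%g, %g] retain negligible gamma mass (%.2g)",
                 dist$trunc[1], dist$trunc[2], mass))
  out <- numeric(0)
  while (length(out) < n) {
    d <- rgamma(max(n, ceiling((n - length(out)) / mass * 1.3)),
                dist$shape, scale = dist$scale)
    out <- c(out, d[d >= dist$trunc[1] & d <= dist$trunc[2]])
  }
  out[seq_len(n)] / 2 * dist$shrink
}

#' Pack disks on a square face
#'
#' Packs the given disks inside the `[0, L]^2` face with no pairwise overlap
#' and no boundary crossing, by random sequential placement followed by
#' repulsive relaxation under an increasing radius ramp.  When `init` is
#' supplied the disks are relaxed from those positions at full radius (used
#' to re-pack a face whose positions come from the dispersion draw).
#'
#' @param L face side (um).
#' @param radii disk radii (um).
#' @param target_density the packing fraction the radii are meant to realise;
#'   the density implied by the radii, `sum(pi r^2)/L^2`, must match it to
#'   within one percentage point.
#' @param seed optional integer seed.
#' @param init optional n x 2 matrix of starting centres.
#' @param max_sweeps relaxation iteration budget.
#' @return n x 2 matrix of disk centres, with the achieved density as
#'   attribute `density`.
#' @export
pack_disks_2d <- function(L, radii, target_density = NULL, seed = NULL,
                          init = NULL, max_sweeps = 6000) {
  if (!is.null(seed)) set.seed(seed)
  radii <- as.numeric(radii)
  if (length(radii) == 0) {
    out <- matrix(numeric(0), 0, 2)
    attr(out, "density") <- 0
    return(out)
  }
  if (any(radii <= 0)) stop("disk radii must be positive")
  if (any(2 * radii > L)) stop("a disk is larger than the face")
  density <- sum(pi * radii^2) / L^2
  if (!is.null(target_density) && abs(density - target_density) > 0.01)
    warning(sprintf("radii imply density %.3f, %.1f pp away from target %.3f",
                    density, 100 * abs(density - target_density), target_density))
  res <- cpp_pack_disks(radii, L, init, final_sweeps = max_sweeps)
  if (!res$converged)
    stop(sprintf("disk packing failed to remove overlaps at density %.3f within %d sweeps",
                 density, max_sweeps))
  out <- res$centres
  attr(out, "density") <- density
  out
}

#' Bundle specification
#'
#' @param L face side of the cuboid (um); fibre endpoints live on the two
#'   `L x L` faces.
#' @param H cuboid height (um), the bundle axis length.
#' @param density target packing density (fraction in (0, 1)).  Targets above
#'   the 2D ceiling of 0.75 are reached later by radial growth: the initial
#'   radii are shrunk so the packed face density is 0.75, and the full-size
#'   radii are recorded for regrowth.
#' @param eta mean angular dispersion (degrees) between fibre chords and the
#'   bundle axis.
#' @param dist a [radius_distribution()].
#' @param seed integer seed.
#' @return Object of class `bundle_spec`.
#' @export
bundle_spec <- function(L = 50, H = L, density = 0.6, eta = 0,
                        dist = radius_distribution(), seed = 1L) {
  if (density <= 0 || density >= 1) stop("target density must be in (0, 1)")
  if (eta < 0) stop("dispersion eta must be >= 0")
  structure(list(L = L, H = H, density = density, eta = eta, dist = dist,
                 seed = as.integer(seed)),
            class = "bundle_spec")
}

#' Crossing specification: two bundles at an inter-bundle angle
#'
#' @param bundle1,bundle2 [bundle_spec()] objects.
#' @param theta inter-bundle angle in degrees, 0 < theta <= 90.
#' @return Object of class `crossing_spec`.
#' @export
crossing_spec <- function(bundle1, bundle2 = bundle1, theta = 90) {
  if (theta <= 0 || theta > 90) stop("crossing angle theta must be in (0, 90]")
  structure(list(bundle1 = bundle1, bundle2 = bundle2, theta = theta),
            class = "crossing_spec")
}

#' Substrate container
#'
#' A substrate is a set of fibre skeletons grouped into bundles inside a
#' cuboid.  `bundles` records per-bundle metadata: the main orientation
#' (`ax, ay, az`), a point on the bundle central axis (`cx, cy, cz`), the
#' dispersion target `eta` and the target density.
#'
#' @param fibres list of [fibre_skeleton()] objects.
#' @param box 2 x 3 matrix, rows are the lower/upper corners (um).
#' @param bundles data frame of bundle metadata.
#' @param seed the seed the substrate was generated from.
#' @return Object of class `substrate`.
#' @export
substrate <- function(fibres, box, bundles = NULL, seed = NA_integer_) {
  box <- as.matrix(box)
  stopifnot(all(dim(box) == c(2, 3)))
  if (is.null(bundles)) {
    cen <- colMeans(box)
    bundles <- data.frame(id = 1L, ax = 0, ay = 0, az = 1,
                          cx = cen[1], cy = cen[2], cz = cen[3],
                          eta = 0, target_density = NA_real_, shrink = 1)
  }
  structure(list(fibres = fibres, box = box, bundles = bundles,
                 seed = seed),
            class = "substrate")
}

#' @export
print.substrate <- function(x, ...) {
  ext <- x$box[2, ] - x$box[1, ]
  cat(sprintf("<substrate> %d fibres, %d bundle(s), box %.3g x %.3g x %.3g um\n",
              length(x$fibres), nrow(x$bundles), ext[1], ext[2], ext[3]))
  invisible(x)
}

# Control-point spacing policy: capsule length between half and twice the
# local radius, refined as radii decrease, floor 1 um spacing cap.
capsule_spacing <- function(r) pmin(2 * r, pmax(0.5 * r, 1))

# Subdivide a straight chord into control points at the spacing policy.
subdivide_chord <- function(a, b, r) {
  len <- sqrt(sum((b - a)^2))
  nseg <- max(1L, as.integer(ceiling(len / capsule_spacing(r))))
  t <- seq(0, 1, length.out = nseg + 1L)
  cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]),
        a[3] + t * (b[3] - a[3]))
}

#' Initialise a single fibre bundle
#'
#' Samples radii from the truncated gamma distribution until the target
#' packing density is reached, packs the corresponding disks on the bottom
#' face, pairs each with a top-face disk displaced laterally to realise the
#' mean angular dispersion `eta` (displacement `H * tan(phi)` with `phi`
#' drawn from a folded normal whose mean equals `eta`, azimuth uniform over
#' the directions that keep the disk inside the face), re-packs the top face
#' from those targets, and connects the paired disks by straight fibres
#' subdivided at the capsule-length policy (spacing between half and twice
#' the local radius).  If the target density exceeds 0.75 the initial radii
#' are shrunk so the packed density is exactly 0.75 and each fibre records
#' its full-size target radius for later regrowth.
#'
#' @param spec a [bundle_spec()].
#' @return A [substrate()] with one bundle whose axis is +Z.
#' @export
init_bundle <- function(spec) {
  stopifnot(inherits(spec, "bundle_spec"))
  set.seed(spec$seed)
  L <- spec$L; H <- spec$H
  ceiling_2d <- 0.75
  # sample radii until the target face density is reached (within one disk)
  r_full <- numeric(0)
  area <- 0
  target_area <- spec$density * L^2
  done <- FALSE
  while (!done) {
    rr <- sample_radii(spec$dist, 64L)
    for (r in rr) {
      a <- pi * r^2
      if (area + a >= target_area) {
        # keep the crossing disk only if it brings us closer to the target
        if (abs(area + a - target_area) <= abs(area - target_area)) {
          r_full <- c(r_full, r); area <- area + a
        }
        done <- TRUE
        break
      }
      r_full <- c(r_full, r); area <- area + a
    }
  }
  shrink <- if (spec$density > ceiling_2d) sqrt(ceiling_2d / spec$density) else 1
  r_pack <- r_full * shrink
  bottom <- pack_disks_2d(L, r_pack)
  n <- length(r_pack)
  if (spec$eta > 0) {
    eta_rad <- spec$eta * pi / 180
    phi <- abs(rnorm(n, mean = eta_rad, sd = eta_rad / 3))
    d <- H * tan(phi)
    tx <- numeric(n); ty <- numeric(n)
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in 1:200) {
        psi <- runif(1, 0, 2 * pi)
        cx <- bottom[i, 1] + d[i] * cos(psi)
        cy <- bottom[i, 2] + d[i] * sin(psi)
        if (cx >= r_pack[i] && cx <= L - r_pack[i] &&
            cy >= r_pack[i] && cy <= L - r_pack[i]) { ok <- TRUE; break }
      }
      if (!ok) { cx <- bottom[i, 1]; cy <- bottom[i, 2] }   # rare: keep vertical
      tx[i] <- cx; ty[i] <- cy
    }
    top <- pack_disks_2d(L, r_pack, init = cbind(tx, ty))
  } else {
    top <- bottom
  }
  fibres <- vector("list", n)
  for (i in seq_len(n)) {
    pts <- subdivide_chord(c(bottom[i, ], 0), c(top[i, ], H), r_pack[i])
    m <- nrow(pts)
    fibres[[i]] <- fibre_skeleton(pts, rep(r_pack[i], m), id = i, bundle = 1L,
                                  target_radii = rep(r_full[i], m))
  }
  bundles <- data.frame(id = 1L, ax = 0, ay = 0, az = 1,
                        cx = L / 2, cy = L / 2, cz = H / 2,
                        eta = spec$eta, target_density = spec$density,
                        shrink = shrink)
  s <- substrate(fibres, rbind(c(0, 0, 0), c(L, L, H)), bundles,
                 seed = spec$seed)
  attr(s, "dist") <- spec$dist
  attr(s, "reference") <- s
  s
}

# Apply a rigid transform (rotation Q then translation tr) to a substrate.
transform_substrate <- function(s, Q, tr = c(0, 0, 0)) {
  for (i in seq_along(s$fibres))
    s$fibres[[i]]$points <- sweep(s$fibres[[i]]$points %*% t(Q), 2, -tr)
  corners <- as.matrix(expand.grid(s$box[, 1], s$box[, 2], s$box[, 3]))
  tc <- sweep(corners %*% t(Q), 2, -tr)
  s$box <- rbind(apply(tc, 2, min), apply(tc, 2, max))
  ax <- as.matrix(s$bundles[, c("ax", "ay", "az")]) %*% t(Q)
  cen <- sweep(as.matrix(s$bundles[, c("cx", "cy", "cz")]) %*% t(Q), 2, -tr)
  s$bundles[, c("ax", "ay", "az")] <- ax
  s$bundles[, c("cx", "cy", "cz")] <- cen
  if (!is.null(attr(s, "reference"))) {
    ref <- attr(s, "reference")
    for (i in seq_along(ref$fibres))
      ref$fibres[[i]]$points <- sweep(ref$fibres[[i]]$points %*% t(Q), 2, -tr)
    attr(s, "reference") <- ref
  }
  s
}

#' Initialise a two-bundle crossing
#'
#' Both bundles are built in their own cuboids (axis +Z), then moved by rigid
#' transforms only: bundle 1 is rotated onto the +X axis, bundle 2 onto the
#' direction at `theta` degrees from +X in the XY plane, and both are centred
#' on the origin.  Rigid motion preserves all fibre lengths, radii and
#' intra-bundle dispersion; inter-bundle overlaps created by the
#' superposition are removed later by [optimize_substrate()].
#'
#' @param spec a [crossing_spec()].
#' @return A [substrate()] with two bundles.
#' @export
init_crossing <- function(spec) {
  stopifnot(inherits(spec, "crossing_spec"))
  s1 <- init_bundle(spec$bundle1)
  b2spec <- spec$bundle2
  b2spec$seed <- b2spec$seed + 1L   # independent draws for the second bundle
  s2 <- init_bundle(b2spec)
  rot_y90 <- rbind(c(0, 0, 1), c(0, 1, 0), c(-1, 0, 0))   # z -> x
  th <- spec$theta * pi / 180
  rot_z <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Q2 <- rot_z %*% rot_y90
  s1 <- transform_substrate(s1, rot_y90, as.numeric(-(rot_y90 %*% colMeans(s1$box))))
  s2 <- transform_substrate(s2, Q2, as.numeric(-(Q2 %*% colMeans(s2$box))))
  n1 <- length(s1$fibres)
  for (i in seq_along(s2$fibres)) {
    s2$fibres[[i]]$id <- n1 + i
    s2$fibres[[i]]$bundle <- 2L
  }
  b2 <- s2$bundles; b2$id <- 2L
  box <- rbind(pmin(s1$box[1, ], s2$box[1, ]), pmax(s1$box[2, ], s2$box[2, ]))
  out <- substrate(c(s1$fibres, s2$fibres), box,
                   rbind(s1$bundles, b2), seed = spec$bundle1$seed)
  attr(out, "dist") <- attr(s1, "dist")
  ref1 <- attr(s1, "reference"); ref2 <- attr(s2, "reference")
  ref <- out
  ref$fibres <- c(ref1$fibres, ref2$fibres)
  attr(out, "reference") <- ref
  attr(out, "theta") <- spec$theta
  out
}

# Clip a polyline (with radii) to an axis-aligned box; returns the longest
# run of the chain inside the box, with boundary intersection points added.
clip_polyline_box <- function(P, R, lo, hi) {
  m <- nrow(P)
  inside <- function(p) all(p >= lo - 1e-9) && all(p <= hi + 1e-9)
  segs <- list()
  cur_P <- NULL; cur_R <- NULL
  add_pt <- function(p, r) {
    cur_P <<- rbind(cur_P, p); cur_R <<- c(cur_R, r)
  }
  flush <- function() {
    if (!is.null(cur_P) && nrow(cur_P) >= 2) segs[[length(segs) + 1L]] <<-
        list(P = cur_P, R = cur_R)
    cur_P <<- NULL; cur_R <<- NULL
  }
  for (i in seq_len(m - 1)) {
    a <- P[i, ]; b <- P[i + 1, ]
    ra <- R[i]; rb <- R[i + 1]
    # slab clipping of segment a->b
    t0 <- 0; t1 <- 1
    d <- b - a
    okseg <- TRUE
    for (k in 1:3) {
      if (abs(d[k]) < 1e-12) {
        if (a[k] < lo[k] - 1e-9 || a[k] > hi[k] + 1e-9) { okseg <- FALSE; break }
      } else {
        ta <- (lo[k] - a[k]) / d[k]; tb <- (hi[k] - a[k]) / d[k]
        if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
        t0 <- max(t0, ta); t1 <- min(t1, tb)
        if (t0 > t1) { okseg <- FALSE; break }
      }
    }
    if (!okseg) { flush(); next }
    pa <- a + t0 * d; pb <- a + t1 * d
    rpa <- ra + t0 * (rb - ra); rpb <- ra + t1 * (rb - ra)
    if (is.null(cur_P)) add_pt(pa, rpa)
    else if (sqrt(sum((cur_P[nrow(cur_P), ] - pa)^2)) > 1e-9) { flush(); add_pt(pa, rpa) }
    add_pt(pb, rpb)
    if (t1 < 1) flush()
  }
  flush()
  if (length(segs) == 0) return(NULL)
  lens <- vapply(segs, function(sg) {
    sum(sqrt(rowSums((sg$P[-1, , drop = FALSE] - sg$P[-nrow(sg$P), , drop = FALSE])^2)))
  }, numeric(1))
  segs[[which.max(lens)]]
}

#' Trim a crossing substrate to its central region
#'
#' After optimization, only fibres that intersect the central crossing region
#' truly belong to the crossing; boundary fibres are discarded and the
#' retained trajectories are clipped to the region box, re-terminating each
#' capsule chain at the clip planes.
#'
#' @param s an (optimized) [substrate()].
#' @param region 2 x 3 matrix (lower/upper corners, um); default is the
#'   central axis-aligned cube with half the box side.
#' @return The trimmed [substrate()]; errors if no fibre intersects the region.
#' @export
trim_crossing <- function(s, region = NULL) {
  stopifnot(inherits(s, "substrate"))
  if (is.null(region)) {
    cen <- colMeans(s$box)
    half <- min(s$box[2, ] - s$box[1, ]) / 4
    region <- rbind(cen - half, cen + half)
  }
  fibres <- list()
  for (f in s$fibres) {
    cl <- clip_polyline_box(f$points, f$radii, region[1, ], region[2, ])
    if (is.null(cl)) next
    tgt <- f$target_radii[1]
    fibres[[length(fibres) + 1L]] <-
      fibre_skeleton(cl$P, cl$R, id = length(fibres) + 1L, bundle = f$bundle,
                     target_radii = rep(tgt, length(cl$R)))
  }
  if (length(fibres) == 0) stop("trim region contains no fibres")
  b <- s$bundles
  cen <- colMeans(region)
  b$cx <- cen[1]; b$cy <- cen[2]; b$cz <- cen[3]
  out <- substrate(fibres, region, b, seed = s$seed)
  attr(out, "dist") <- attr(s, "dist")
  attr(out, "reference") <- out
  out
}
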