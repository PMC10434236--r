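#' Growth policy for fibre radial growth
#'
#' @param seeding `"uniform"` seeds every voxel of the capsule interiors
#'   (smooth fronts, radius variation confined to a narrow band);
#'   `"random"` keeps a random fraction of capsule voxels as seeds, which
#'   de-synchronises the fronts and adds surface irregularity (radius
#'   variation up to about half the local radius).
#' @param iterations maximum number of breadth-first growth layers (one
#'   layer adds at most one voxel of radial extent).
#' @param cap_factor per-fibre radius cap as a multiple of the full-size
#'   target radius; growth never claims a voxel farther than
#'   `cap_factor * r_target` from the fibre skeleton.  1 restores the target
#'   radii; the max-density preset raises it to 1.5 so fibres can fill the
#'   pockets between cylindrical shapes.
#' @param seed_keep fraction of capsule voxels kept as seeds under random
#'   seeding.
#' @param seed integer seed for the randomised growth order.
#' @return Object of class `growth_policy`.
#' @export
growth_policy <- function(seeding = c("uniform", "random"), iterations = 1000L,
                          cap_factor = 1.0, seed_keep = 0.05, seed = 1L) {
  seeding <- match.arg(seeding)
  if (iterations < 0) stop("iterations must be >= 0")
  if (cap_factor < 1) stop("cap_factor must be >= 1 (cap below the target radius)")
  structure(list(seeding = seeding, iterations = as.integer(iterations),
                 cap_factor = cap_factor, seed_keep = seed_keep,
                 seed = as.integer(seed)),
            class = "growth_policy")
}

#' Voxel ownership grid
#'
#' Discretisation of the substrate box: each voxel is unclaimed (0, the
#' extracellular space) or owned by exactly one fibre's outer mask; a
#' parallel `inner` field marks the axonal masks after erosion
#' ([erode_inner()]).  The `owner` and `inner` fields are disjoint by
#' construction (one owner per voxel) and `inner` is a subset of `owner`.
#' Note: for memory efficiency the growth and erosion operations update the
#' grid fields in place.
#'
#' @param owner,seg,inner integer fields (length `prod(dim)`).
#' @param dim voxel dimensions.
#' @param res voxel edge (um).
#' @param origin box lower corner (um).
#' @param nfib number of fibres.
#' @return Object of class `voxel_grid`.
#' @keywords internal
voxel_grid <- function(owner, seg, dim, res, origin, nfib, inner = NULL) {
  structure(list(owner = owner, seg = seg, inner = inner,
                 dim = as.integer(dim), res = res, origin = as.numeric(origin),
                 nfib = as.integer(nfib)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels at %.3g um, %d fibres, FVF %.1f%%%s\n",
              x$dim[1], x$dim[2], x$dim[3], x$res, x$nfib,
              100 * mean(x$owner > 0),
              if (is.null(x$inner)) "" else sprintf(", AVF %.1f%%", 100 * mean(x$inner > 0))))
  invisible(x)
}

#' Rasterize capsule chains into a voxel ownership grid
#'
#' Claims every voxel whose centre lies inside a fibre's capsule chain.
#' Because the substrate is overlap-free, conflicts can only arise from
#' discretisation at touching surfaces and are resolved deterministically
#' (lowest fibre id wins).  The resolution must put at least five voxels
#' across the smallest full-size (target) fibre diameter — radii may be
#' transiently smaller after optimization, but the grid has to resolve the
#' geometry the fibres grow back to.
#'
#' @param s an overlap-free [substrate()].
#' @param resolution voxel edge (um); default
#'   `min(0.1, 2 * min(target radius) / 5)`.
#' @param pad margin added around the substrate box (um).
#' @return A [voxel_grid()].
#' @export
rasterize_capsules <- function(s, resolution = NULL, pad = 0) {
  stopifnot(inherits(s, "substrate"))
  if (length(s$fibres) == 0) {
    if (is.null(resolution)) resolution <- 0.1
    lo <- s$box[1, ] - pad; hi <- s$box[2, ] + pad
    dim <- as.integer(ceiling((hi - lo) / resolution - 1e-9))
    n <- prod(dim)
    return(voxel_grid(integer(n), integer(n), dim, resolution, lo, 0L))
  }
  rmin <- min(vapply(s$fibres, function(f) min(f$target_radii), numeric(1)))
  if (is.null(resolution)) resolution <- min(0.1, 2 * rmin / 5)
  if (resolution > 2 * rmin / 5 + 1e-12)
    stop(sprintf(
      "resolution %.3g um too coarse: need at least 5 voxels across the smallest diameter (%.3g um)",
      resolution, 2 * rmin))
  lo <- s$box[1, ] - pad; hi <- s$box[2, ] + pad
  dim <- as.integer(ceiling((hi - lo) / resolution - 1e-9))
  arr <- substrate_arrays(s)
  ras <- cpp_rasterize(dim, resolution, lo, arr$P, arr$R, arr$capA, arr$capF)
  voxel_grid(ras$owner, ras$seg, dim, resolution, lo, length(s$fibres))
}

#' Fibre radial growth
#'
#' Densifies the substrate by iterative breadth-first expansion of the fibre
#' masks: each layer adds, in seeded random order, unclaimed voxels
#' 6-adjacent to a fibre's mask whose centre lies within the fibre's capped
#' radius of its skeleton.  Masks can come into contact but never
#' interpenetrate (a voxel has one owner), stay connected, and the total
#' fibre volume is non-decreasing per iteration.  Growth stops at the
#' iteration budget, when nothing more can be claimed, or when the fibre
#' volume fraction in `region` reaches `stop_fvf` (checked voxel-exactly, so
#' a target FVF can be hit mid-layer).
#'
#' @param grid a [voxel_grid()] from [rasterize_capsules()]; modified in
#'   place and returned.
#' @param s the substrate (skeletons provide the radius caps).
#' @param policy a [growth_policy()].
#' @param stop_fvf optional target fibre volume fraction in the analysis
#'   region.
#' @param region 2 x 3 matrix of the analysis region (um); default the
#'   central 80% of the box per axis.
#' @return The grown [voxel_grid()], with growth statistics as attribute
#'   `growth`.
#' @export
grow_fibres <- function(grid, s, policy = growth_policy(), stop_fvf = NULL,
                        region = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(s, "substrate"))
  set.seed(policy$seed)
  arr <- substrate_arrays(s)
  capR <- arr$Rt * policy$cap_factor
  if (policy$seeding == "random")
    cpp_thin_mask(grid$owner, grid$seg, policy$seed_keep)
  reg <- region_to_voxels(grid, region)
  stop_count <- -1
  if (!is.null(stop_fvf)) {
    nreg <- prod(reg$hi - reg$lo + 1L)
    stop_count <- stop_fvf * nreg
  }
  gr <- cpp_grow(grid$owner, grid$seg, grid$dim, grid$res, grid$origin,
                 arr$P, capR, arr$capA, arr$capF, arr$fibCapLo, arr$fibCapHi,
                 policy$iterations, stop_count, reg$lo, reg$hi)
  attr(grid, "growth") <- gr
  grid
}

# Convert a um-space region (2 x 3) to inclusive voxel index bounds (0-based);
# default central 80% per axis.
region_to_voxels <- function(grid, region = NULL) {
  lo_um <- grid$origin
  hi_um <- grid$origin + grid$dim * grid$res
  if (is.null(region)) {
    cen <- (lo_um + hi_um) / 2
    half <- 0.4 * (hi_um - lo_um)
    region <- rbind(cen - half, cen + half)
  }
  lo <- pmax(0L, as.integer(floor((region[1, ] - grid$origin) / grid$res)))
  hi <- pmin(grid$dim - 1L, as.integer(ceiling((region[2, ] - grid$origin) / grid$res)) - 1L)
  if (any(hi < lo)) stop("empty analysis region")
  list(lo = lo, hi = hi, region = region)
}

#' Rewrite fibre radii to follow a longitudinal pattern
#'
#' Overwrites the per-control-point radii of a fibre so the grown mesh
#' exhibits prescribed radius variation along its length, e.g. a periodic
#' oscillation between 1 and 2 um per capsule.  Shared control points keep a
#' single radius, so capsule-to-capsule continuity is preserved.
#'
#' @param f a [fibre_skeleton()].
#' @param pattern either a numeric vector of radii (recycled along the
#'   control points) or a list `list(amplitude = , period = )` with the
#'   amplitude as a fraction of the current radius and the period in
#'   capsules (a sinusoidal modulation within `[-amplitude, +amplitude]`).
#' @return The modified fibre; errors if any resulting radius is <= 0.
#' @export
radius_modulation <- function(f, pattern) {
  stopifnot(inherits(f, "fibre_skeleton"))
  m <- nrow(f$points)
  if (is.numeric(pattern)) {
    radii <- rep_len(pattern, m)
  } else {
    amp <- pattern$amplitude
    per <- pattern$period
    if (is.null(amp) || is.null(per)) stop("pattern needs amplitude and period")
    if (abs(amp) > 0.5 + 1e-9)
      amp <- sign(amp) * 0.5   # clamp variation to [-r/2, +r/2]
    radii <- f$radii * (1 + amp * sin(2 * pi * (seq_len(m) - 1) / per))
  }
  if (any(radii <= 0)) stop("radius modulation produced non-positive radii")
  f$radii <- radii
  f$target_radii <- radii
  f
}

#' Erode outer masks to carve the inner (axonal) compartment
#'
#' The inner mask of each fibre is the morphological erosion
#' (6-connectivity) of its outer mask by a per-fibre depth `k_f`, so the
#' shell between the two surfaces is the myelin compartment.  Depths start
#' at `k_f = round(r_f * (1 - g) / res)` from the aggregate g-ratio relation
#' and are then refined per fibre (+-1 voxel, largest fibres first) so the
#' substrate-level myelin volume best matches the target.  On the grid the
#' identity AVF + MVF = FVF holds exactly.
#'
#' @param grid a grown [voxel_grid()]; the `inner` field is filled in place.
#' @param s the substrate.
#' @param g_target target aggregate g-ratio (fraction), or `NULL` if
#'   `mvf_target` is given.
#' @param mvf_target optional target myelin volume fraction of the analysis
#'   region (overrides `g_target` for the refinement step).
#' @param region analysis region (2 x 3 um matrix); default central 80%.
#' @return The [voxel_grid()] with `inner` filled; fibres annihilated by
#'   erosion (empty inner mask) are recorded in attribute
#'   `unmyelinated_thin` with a warning.
#' @export
erode_inner <- function(grid, s, g_target = 0.7, mvf_target = NULL,
                        region = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(g_target) && is.null(mvf_target))
    stop("need g_target or mvf_target")
  depth <- cpp_depth(grid$owner, grid$dim)
  reg <- region_to_voxels(grid, region)
  hist <- cpp_depth_hist(grid$owner, depth, grid$nfib, grid$dim, reg$lo, reg$hi)
  cnt0 <- cpp_region_counts(grid$owner, NULL, grid$dim, reg$lo, reg$hi, grid$nfib)
  r_out <- vapply(s$fibres, function(f) max(f$target_radii), numeric(1))
  if (is.null(g_target))
    g_target <- sqrt(max(0, 1 - mvf_target * cnt0$total / max(cnt0$outer, 1)))
  kf <- pmax(0L, as.integer(round(r_out * (1 - g_target) / grid$res)))
  maxd <- ncol(hist)
  # myelin voxels of fibre f at erosion depth k are those with depth <= k
  cum <- t(apply(hist, 1, cumsum))           # nfib x maxd (analysis region)
  total_f <- cum[, maxd]
  myelin_at <- function(kf) {
    k <- pmin(pmax(kf, 0L), maxd)
    out <- numeric(grid$nfib)
    nz <- k > 0
    out[nz] <- cum[cbind(which(nz), k[nz])]
    out
  }
  target_myelin <- if (!is.null(mvf_target)) mvf_target * cnt0$total
  else (1 - g_target^2) * cnt0$outer   # from MVF/FVF = 1 - g^2
  # greedy per-fibre refinement (+-1 voxel), largest fibres first
  ord <- order(total_f, decreasing = TRUE)
  my_f <- myelin_at(kf)
  cur <- sum(my_f)
  my_of <- function(i, k) if (k <= 0) 0 else cum[i, min(k, maxd)]
  for (pass in 1:2) {
    for (i in ord) {
      for (step in c(1L, -1L)) {
        k2 <- kf[i] + step
        if (k2 < 0) next
        new <- cur - my_f[i] + my_of(i, k2)
        if (abs(new - target_myelin) < abs(cur - target_myelin)) {
          kf[i] <- k2
          my_f[i] <- my_of(i, k2)
          cur <- new
        }
      }
    }
  }
  inner <- cpp_make_inner(grid$owner, depth, kf)
  grid$inner <- inner
  full <- list(lo = c(0L, 0L, 0L), hi = grid$dim - 1L)
  out_f <- cpp_region_counts(grid$owner, NULL, grid$dim, full$lo, full$hi,
                             grid$nfib)$per_fibre_outer
  in_f <- cpp_region_counts(inner, NULL, grid$dim, full$lo, full$hi,
                            grid$nfib)$per_fibre_outer
  empty <- which(out_f > 0 & in_f == 0)
  if (length(empty) > 0) {
    warning(sprintf("%d fibre(s) fully eroded (unmyelinated-thin): ids %s",
                    length(empty), paste(utils::head(empty, 5), collapse = ", ")))
  }
  attr(grid, "erosion") <- list(kf = kf, g_target = g_target)
  attr(grid, "unmyelinated_thin") <- empty
  grid
}
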