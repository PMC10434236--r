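#' Volume fractions of a grown grid
#'
#' Voxel-count ratios over the analysis region: fibre (FVF, outer masks),
#' axon (AVF, inner masks), myelin (MVF = FVF - AVF) and extracellular
#' (EVF = 1 - FVF).  The identities `AVF + MVF = FVF` and `FVF + EVF = 1`
#' hold exactly because every voxel has exactly one owner.
#'
#' @param grid a [voxel_grid()] (with `inner` filled; otherwise AVF = FVF
#'   and MVF = 0 are reported for the unmyelinated grid).
#' @param region 2 x 3 um matrix; default the central 80% of the box per
#'   axis (boundary artefacts excluded).
#' @return Named numeric vector `(AVF, MVF, FVF, EVF)` (fractions).
#' @export
volume_fractions <- function(grid, region = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  reg <- region_to_voxels(grid, region)
  cnt <- cpp_region_counts(grid$owner, grid$inner, grid$dim, reg$lo, reg$hi,
                           grid$nfib)
  if (cnt$total == 0) stop("empty analysis region")
  fvf <- cnt$outer / cnt$total
  avf <- if (is.null(grid$inner)) fvf else cnt$inner / cnt$total
  c(AVF = avf, MVF = fvf - avf, FVF = fvf, EVF = 1 - fvf)
}

#' Aggregate g-ratio from volume fractions
#'
#' The aggregate g-ratio of a substrate relates the myelin and fibre volume
#' fractions through `g = sqrt(1 - MVF/FVF) = sqrt(AVF/FVF)` (the
#' volume-based aggregate relation): myelin occupies the shell between the
#' inner and outer surfaces, so the inner/outer *area* ratio of the average
#' fibre is the fraction under the square root.
#'
#' @param MVF myelin volume fraction.
#' @param FVF fibre volume fraction (> 0), same units as `MVF` (both
#'   percentages or both fractions).
#' @return g-ratio as a fraction in (0, 1]; multiply by 100 for percent.
#' @examples
#' 100 * g_ratio(35, 60)   # 64.5
#' 100 * g_ratio(43, 68)   # 60.6
#' @export
g_ratio <- function(MVF, FVF) {
  if (any(FVF <= 0)) stop("FVF must be positive")
  if (any(MVF < 0) || any(MVF > FVF)) stop("need 0 <= MVF <= FVF")
  sqrt(1 - MVF / FVF)
}

#' Equivalent-radius profile of a fibre mesh
#'
#' Slices the mesh with planes orthogonal to the local skeleton tangent at
#' regular arc-length steps; at each step the cross-section polygon
#' containing the skeleton point is found and the equivalent radius is that
#' of the circle with the same area, `sqrt(area / pi)`.  Steps where no
#' cross-section contains the skeleton point (e.g. slices beyond the fibre
#' caps) are flagged `NA`, never interpolated.
#'
#' @param mesh a [surface_mesh()].
#' @param skeleton the fibre's [fibre_skeleton()] (interior to the mesh).
#' @param step arc-length sampling interval (um), default 1.
#' @return Data frame with `arc_position` (um), `radius` (um, `NA` when
#'   missing) and `area` (um^2).
#' @export
equivalent_radius_profile <- function(mesh, skeleton, step = 1) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(skeleton, "fibre_skeleton"))
  P <- skeleton$points
  seg <- P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE]
  seglen <- sqrt(rowSums(seg^2))
  arc <- c(0, cumsum(seglen))
  total <- arc[length(arc)]
  targets <- seq(step / 2, total - step / 4, by = step)
  if (length(targets) == 0) targets <- total / 2
  V <- mesh$vertices; F <- mesh$faces
  out <- data.frame(arc_position = targets, radius = NA_real_, area = NA_real_)
  for (i in seq_along(targets)) {
    tpos <- targets[i]
    j <- findInterval(tpos, arc, rightmost.closed = TRUE)
    j <- min(max(j, 1L), nrow(P) - 1L)
    frac <- (tpos - arc[j]) / max(seglen[j], 1e-12)
    x0 <- P[j, ] + frac * seg[j, ]
    tang <- seg[j, ] / max(seglen[j], 1e-12)
    # average tangent with neighbours for a smoother normal direction
    if (j > 1) tang <- tang + seg[j - 1, ] / max(seglen[j - 1], 1e-12)
    if (j < nrow(seg)) tang <- tang + seg[j + 1, ] / max(seglen[j + 1], 1e-12)
    tang <- tang / sqrt(sum(tang^2))
    poly <- slice_mesh(V, F, x0, tang)
    if (is.null(poly)) next
    # in-plane basis
    ref <- if (abs(tang[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * tang) * tang; u <- u / sqrt(sum(u^2))
    w <- c(tang[2] * u[3] - tang[3] * u[2],
           tang[3] * u[1] - tang[1] * u[3],
           tang[1] * u[2] - tang[2] * u[1])
    best_area <- NA_real_
    for (loop in poly) {
      lx <- (loop %*% u) - sum(x0 * u)
      ly <- (loop %*% w) - sum(x0 * w)
      # shoelace area & point-in-polygon for the origin (= skeleton point)
      n <- length(lx)
      xs <- as.numeric(lx); ys <- as.numeric(ly)
      a2 <- sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)
      inside <- point_in_polygon(0, 0, xs, ys)
      if (inside) { best_area <- abs(a2) / 2; break }
    }
    if (!is.na(best_area)) {
      out$area[i] <- best_area
      out$radius[i] <- sqrt(best_area / pi)
    }
  }
  out
}

# Intersect a triangle mesh with the plane (x - x0) . n = 0; returns a list
# of closed loops (each an m x 3 matrix of ordered intersection points).
slice_mesh <- function(V, F, x0, n) {
  d <- as.numeric(V %*% n) - sum(x0 * n)
  d[d == 0] <- 1e-12
  s1 <- d[F[, 1]]; s2 <- d[F[, 2]]; s3 <- d[F[, 3]]
  crossing <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  idx <- which(crossing)
  if (length(idx) == 0) return(NULL)
  # for each crossing triangle find its two crossed edges (keyed by vertex pair)
  edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  pt_cache <- new.env(parent = emptyenv())
  edge_point <- function(a, b) {
    k <- edge_key(a, b)
    p <- pt_cache[[k]]
    if (!is.null(p)) return(list(key = k, p = p))
    t <- d[a] / (d[a] - d[b])
    p <- V[a, ] + t * (V[b, ] - V[a, ])
    pt_cache[[k]] <- p
    list(key = k, p = p)
  }
  # adjacency: edge key -> the (up to 2) neighbouring edge keys via triangles
  links <- list()
  pts <- list()
  for (f in idx) {
    vv <- F[f, ]
    dd <- d[vv]
    ek <- character(0)
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      if (dd[e[1]] * dd[e[2]] < 0) {
        ep <- edge_point(vv[e[1]], vv[e[2]])
        ek <- c(ek, ep$key)
        pts[[ep$key]] <- ep$p
      }
    }
    if (length(ek) == 2)
      links[[length(links) + 1L]] <- ek
  }
  if (length(links) == 0) return(NULL)
  adj <- new.env(parent = emptyenv())
  for (l in links) {
    adj[[l[1]]] <- c(adj[[l[1]]], l[2])
    adj[[l[2]]] <- c(adj[[l[2]]], l[1])
  }
  visited <- new.env(parent = emptyenv())
  loops <- list()
  for (start in names(pts)) {
    if (!is.null(visited[[start]])) next
    loop_keys <- character(0)
    cur <- start; prev <- ""
    repeat {
      visited[[cur]] <- TRUE
      loop_keys <- c(loop_keys, cur)
      nb <- adj[[cur]]
      nb <- nb[nb != prev]
      nxt <- NA_character_
      for (cand in nb) if (is.null(visited[[cand]])) { nxt <- cand; break }
      if (is.na(nxt)) break
      prev <- cur; cur <- nxt
    }
    if (length(loop_keys) >= 3)
      loops[[length(loops) + 1L]] <- do.call(rbind, lapply(loop_keys, function(k) pts[[k]]))
  }
  loops
}

point_in_polygon <- function(px, py, xs, ys) {
  n <- length(xs)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((ys[i] > py) != (ys[j] > py) &&
        px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
      inside <- !inside
    j <- i
  }
  inside
}

#' Per-fibre mean radii and distance to the target distribution
#'
#' The global radii distribution of a substrate uses the mean equivalent
#' radius of each fibre (over its profile).  The distance to the truncated
#' target gamma distribution is the Wasserstein-1 distance (robust for small
#' fibre counts), with the Kolmogorov-Smirnov statistic reported alongside.
#' Distances are computed on the diameter scale.
#'
#' @param mean_radii numeric vector of per-fibre mean equivalent radii (um).
#' @param dist the target [radius_distribution()].
#' @return List with `mean_radii`, `wasserstein1` (um), `ks` and the target
#'   mean diameter.
#' @export
radii_distribution <- function(mean_radii, dist = radius_distribution()) {
  mean_radii <- mean_radii[!is.na(mean_radii)]
  if (length(mean_radii) == 0) stop("no fibre mean radii")
  diam <- sort(2 * mean_radii)
  lo <- dist$trunc[1]; hi <- dist$trunc[2]
  Zlo <- pgamma(lo, dist$shape, scale = dist$scale)
  Z <- pgamma(hi, dist$shape, scale = dist$scale) - Zlo
  target_cdf <- function(x)
    pmin(1, pmax(0, (pgamma(pmin(pmax(x, lo), hi), dist$shape,
                            scale = dist$scale) - Zlo) / Z))
  grid <- seq(lo, hi, length.out = 2001L)
  emp_cdf <- vapply(grid, function(x) mean(diam <= x), numeric(1))
  tc <- target_cdf(grid)
  w1 <- sum(abs(emp_cdf - tc)) * (grid[2] - grid[1])
  ks <- max(abs(emp_cdf - tc))
  list(mean_radii = mean_radii, wasserstein1 = w1, ks = ks,
       target_mean_diameter = truncated_gamma_mean(dist))
}

#' Mean angular dispersion of a bundle
#'
#' Each fibre's main orientation is the unit chord from its first to its
#' last control point; the dispersion is the mean angle (degrees) between
#' these chords and the bundle axis.
#'
#' @param fibres list of [fibre_skeleton()] (or a [substrate()], optionally
#'   filtered by `bundle`).
#' @param axis bundle main orientation (3-vector).
#' @param bundle bundle id when a substrate is given.
#' @return Mean angle in degrees, with per-fibre angles as attribute
#'   `angles`.
#' @export
dispersion_angle <- function(fibres, axis = c(0, 0, 1), bundle = NULL) {
  if (inherits(fibres, "substrate")) {
    s <- fibres
    if (!is.null(bundle)) {
      b <- s$bundles[s$bundles$id == bundle, ]
      axis <- c(b$ax, b$ay, b$az)
      fibres <- Filter(function(f) f$bundle == bundle, s$fibres)
    } else {
      fibres <- s$fibres
    }
  }
  if (length(fibres) == 0) stop("no fibres")
  axis <- axis / sqrt(sum(axis^2))
  ang <- vapply(fibres, function(f) {
    chord <- f$points[nrow(f$points), ] - f$points[1, ]
    len <- sqrt(sum(chord^2))
    if (len < 1e-12) stop(sprintf("fibre %d has a zero-length chord", f$id))
    acos(pmin(1, abs(sum(chord / len * axis)))) * 180 / pi
  }, numeric(1))
  structure(mean(ang), angles = ang)
}

#' Full metrics report for a grown substrate
#'
#' Bundles the voxel-based volume fractions, the aggregate g-ratio, mesh
#' volumes (when meshes are supplied), per-bundle dispersion and the
#' radii-distribution distance into one report.
#'
#' @param grid a [voxel_grid()] with inner masks.
#' @param s the substrate.
#' @param meshes optional list of outer-surface meshes (from
#'   [fibre_meshes()]) used for the mesh-based FVF cross-check and the
#'   radii distribution.
#' @param region analysis region.
#' @param profile_step arc-length step for equivalent-radius profiles (um).
#' @return Object of class `metrics_report` (a list).
#' @export
substrate_metrics <- function(grid, s, meshes = NULL, region = NULL,
                              profile_step = 1) {
  vf <- volume_fractions(grid, region)
  g <- if (vf[["FVF"]] > 0) g_ratio(vf[["MVF"]], vf[["FVF"]]) else NA_real_
  disp <- lapply(s$bundles$id, function(b) dispersion_angle(s, bundle = b))
  names(disp) <- paste0("bundle_", s$bundles$id)
  rep <- list(AVF = vf[["AVF"]], MVF = vf[["MVF"]], FVF = vf[["FVF"]],
              EVF = vf[["EVF"]], g_ratio = g,
              dispersion = vapply(disp, as.numeric, numeric(1)))
  if (!is.null(meshes)) {
    prof <- profile_all_fibres(meshes, s, profile_step)
    rep$mean_equivalent_radii <- prof$mean_radii
    rep$profiles <- prof$profiles
    dist <- attr(s, "dist")
    if (!is.null(dist)) {
      rd <- radii_distribution(prof$mean_radii, dist)
      rep$radii_wasserstein1 <- rd$wasserstein1
      rep$radii_ks <- rd$ks
    }
    box_vol <- prod(s$box[2, ] - s$box[1, ])
    rep$mesh_FVF <- sum(vapply(meshes, mesh_volume, numeric(1))) / box_vol
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> AVF %.1f%%  MVF %.1f%%  FVF %.1f%%  EVF %.1f%%  g %.3f\n",
              100 * x$AVF, 100 * x$MVF, 100 * x$FVF, 100 * x$EVF, x$g_ratio))
  cat(sprintf("  dispersion (deg): %s\n",
              paste(sprintf("%.2f", x$dispersion), collapse = ", ")))
  if (!is.null(x$radii_wasserstein1))
    cat(sprintf("  radii W1 distance: %.4g um (KS %.3f)\n",
                x$radii_wasserstein1, x$radii_ks))
  invisible(x)
}

# Equivalent-radius profiles for a list of meshes; returns per-fibre means.
profile_all_fibres <- function(meshes, s, step = 1) {
  ids <- vapply(meshes, `[[`, integer(1), "fibre_id")
  profiles <- list()
  means <- rep(NA_real_, length(meshes))
  for (k in seq_along(meshes)) {
    f <- s$fibres[[ids[k]]]
    pr <- equivalent_radius_profile(meshes[[k]], f, step)
    profiles[[paste0("fibre_", ids[k])]] <- pr
    means[k] <- mean(pr$radius, na.rm = TRUE)
  }
  list(profiles = profiles, mean_radii = means)
}

#' Write equivalent-radius profiles as CSV
#'
#' @param profiles named list of profile data frames (`fibre_<id>`), outer
#'   surfaces; optionally a second list for inner surfaces.
#' @param path output CSV.
#' @param inner_profiles optional inner-surface profiles aligned by name.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path, inner_profiles = NULL) {
  rows <- list()
  for (nm in names(profiles)) {
    pr <- profiles[[nm]]
    id <- as.integer(sub("fibre_", "", nm))
    inner <- if (!is.null(inner_profiles) && !is.null(inner_profiles[[nm]]))
      inner_profiles[[nm]]$radius[seq_len(nrow(pr))] else NA_real_
    rows[[nm]] <- data.frame(fibre_id = id, arc_position_um = pr$arc_position,
                             outer_radius_um = pr$radius,
                             inner_radius_um = inner)
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
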