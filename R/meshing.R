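#' Surface mesh of one fibre compartment
#'
#' Triangle mesh (vertices in um, 1-based vertex index triples) of a fibre's
#' outer or inner surface.  Meshes produced by [mask_to_mesh()] are closed,
#' consistently oriented 2-manifolds, as required by mesh-based Monte Carlo
#' diffusion simulators.
#'
#' @param vertices numeric matrix (V x 3), um.
#' @param faces integer matrix (F x 3), 1-based.
#' @param fibre_id integer id.
#' @param kind `"outer"` or `"inner"`.
#' @return Object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, fibre_id = NA_integer_,
                         kind = c("outer", "inner")) {
  kind <- match.arg(kind)
  structure(list(vertices = vertices, faces = faces,
                 fibre_id = as.integer(fibre_id), kind = kind),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> fibre %s (%s): %d vertices, %d faces, volume %.4g um^3\n",
              x$fibre_id, x$kind, nrow(x$vertices), nrow(x$faces),
              mesh_volume(x)))
  invisible(x)
}

#' Enclosed volume of a closed mesh (divergence theorem)
#' @param m a `surface_mesh` (or list with `vertices`, `faces`).
#' @return volume (um^3), positive for outward orientation.
#' @export
mesh_volume <- function(m) {
  V <- m$vertices; F <- m$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
        a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
        a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Total surface area of a mesh
#' @param m a `surface_mesh`.
#' @return area (um^2).
#' @export
mesh_area <- function(m) {
  V <- m$vertices; F <- m$faces
  u <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  w <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Extract a closed surface mesh from a voxel mask
#'
#' Runs marching tetrahedra (the unambiguous tetrahedral decomposition of
#' the voxel-centre lattice) at the 0.5 isosurface of the binary mask.  The
#' result is watertight and consistently oriented by construction; an
#' unbranched fibre yields a single genus-0 component (Euler characteristic
#' 2).
#'
#' @param mask logical array (or vector with `dim` supplied).
#' @param resolution voxel edge (um).
#' @param origin position of the voxel-grid lower corner (um).
#' @param dim voxel dimensions if `mask` has no dim attribute.
#' @param fibre_id,kind metadata passed to [surface_mesh()].
#' @return A [surface_mesh()]; errors on an empty mask or if the mask has
#'   multiple connected components (their count is reported).
#' @export
mask_to_mesh <- function(mask, resolution = 1, origin = c(0, 0, 0),
                         dim = base::dim(mask), fibre_id = NA_integer_,
                         kind = "outer") {
  if (is.null(dim)) stop("mask needs dim")
  if (!any(mask)) stop("empty mask")
  m <- cpp_march_tets(as.logical(mask), as.integer(dim), resolution,
                      as.numeric(origin))
  mesh <- surface_mesh(m$vertices, m$faces, fibre_id, kind)
  nc <- mesh_components(mesh)
  if (nc > 1)
    stop(sprintf("mask produced %d connected surface components; expected 1", nc))
  mesh
}

# Number of connected components of the face graph.
mesh_components <- function(m) {
  cpp_mesh_components(nrow(m$vertices), m$faces)
}

#' Laplacian smoothing followed by edge-collapse decimation
#'
#' Smoothing removes the voxel staircase (uniform Laplacian, relaxation
#' `lambda`), guarded so the enclosed volume never drifts more than
#' `volume_guard` from the input; decimation collapses shortest edges to
#' their midpoints under a manifoldness (link condition) and normal-flip
#' safeguard, so the output remains watertight, with at most
#' `decim_fraction` times the input triangle count (where reachable without
#' breaking the guards).
#'
#' @param m a [surface_mesh()].
#' @param smooth_iters smoothing iterations (default 10).
#' @param lambda relaxation factor in (0, 1].
#' @param decim_fraction target fraction of triangles kept.
#' @param volume_guard maximum relative volume drift (default 2%).
#' @return The processed [surface_mesh()].
#' @export
smooth_and_decimate <- function(m, smooth_iters = 10L, lambda = 0.5,
                                decim_fraction = 0.25, volume_guard = 0.02) {
  stopifnot(inherits(m, "surface_mesh"))
  out <- m
  if (smooth_iters > 0) {
    sm <- cpp_smooth_mesh(out$vertices, out$faces, as.integer(smooth_iters),
                          lambda, volume_guard)
    out$vertices <- sm$vertices
  }
  if (decim_fraction < 1) {
    dc <- cpp_decimate(out$vertices, out$faces, decim_fraction, volume_guard)
    cand <- surface_mesh(dc$vertices, dc$faces, out$fibre_id, out$kind)
    rep <- validate_mesh(cand, check_self_intersections = FALSE)
    if (!rep$watertight || !rep$oriented) {
      warning("decimation would break manifoldness; returning the undecimated mesh")
    } else {
      out <- cand
    }
  }
  out
}

#' Validate a surface mesh for simulator use
#'
#' Report-only checks: watertightness (every directed edge appears exactly
#' once), orientation consistency (every undirected edge is traversed once
#' in each direction), number of connected components, self-intersection
#' count, enclosed volume and area.
#'
#' @param m a [surface_mesh()].
#' @param check_self_intersections run the triangle-triangle test (grid
#'   accelerated; the expensive part of the report).
#' @return A list report.
#' @export
validate_mesh <- function(m, check_self_intersections = TRUE) {
  F <- m$faces
  ed <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  key <- paste(ed[, 1], ed[, 2])
  rkey <- paste(ed[, 2], ed[, 1])
  watertight <- !anyDuplicated(key) && all(key %in% rkey)
  oriented <- watertight   # each directed edge once + its reverse present
  nundirected <- length(unique(ifelse(ed[, 1] < ed[, 2], key, rkey)))
  list(watertight = watertight,
       oriented = oriented,
       components = mesh_components(m),
       euler_characteristic = nrow(m$vertices) - nundirected + nrow(F),
       self_intersections = if (check_self_intersections)
         cpp_self_intersections(m$vertices, m$faces) else NA_integer_,
       volume = mesh_volume(m),
       area = mesh_area(m),
       n_vertices = nrow(m$vertices),
       n_faces = nrow(F))
}

#' Mesh every fibre of a grown grid
#'
#' Crops each fibre's mask to its bounding box, extracts the closed surface,
#' then smooths and decimates it.  Fibres with empty masks are skipped.
#'
#' @param grid a [voxel_grid()] (with `inner` filled if `kind = "inner"`).
#' @param kind `"outer"` or `"inner"`.
#' @param fibres integer ids to mesh (default all).
#' @param smooth_iters,decim_fraction,volume_guard see [smooth_and_decimate()].
#' @return Named list of [surface_mesh()] objects (`fibre_<id>`).
#' @export
fibre_meshes <- function(grid, kind = c("outer", "inner"), fibres = NULL,
                         smooth_iters = 10L, decim_fraction = 0.25,
                         volume_guard = 0.02) {
  kind <- match.arg(kind)
  field <- if (kind == "outer") grid$owner else grid$inner
  if (is.null(field)) stop("grid has no inner field; run erode_inner() first")
  if (is.null(fibres)) fibres <- seq_len(grid$nfib)
  out <- list()
  for (f in fibres) {
    bb <- cpp_label_bbox(field, grid$dim, f)
    if (bb[4] < 0) next
    lo <- bb[1:3]; hi <- bb[4:6]
    sub <- cpp_crop_label(field, grid$dim, f, lo, hi)
    sdim <- hi - lo + 1L
    mesh <- mask_to_mesh(sub, grid$res, grid$origin + lo * grid$res,
                         dim = sdim, fibre_id = f, kind = kind)
    out[[paste0("fibre_", f)]] <-
      smooth_and_decimate(mesh, smooth_iters, decim_fraction = decim_fraction,
                          volume_guard = volume_guard)
  }
  out
}

#' Write a mesh as binary little-endian PLY
#'
#' The format consumed by mesh-based Monte Carlo simulators.
#'
#' @param m a [surface_mesh()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ply <- function(m, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste0(
    "ply\nformat binary_little_endian 1.0\n",
    "comment wmphantom fibre ", m$fibre_id, " ", m$kind, " surface\n",
    "element vertex ", nrow(m$vertices), "\n",
    "property float x\nproperty float y\nproperty float z\n",
    "element face ", nrow(m$faces), "\n",
    "property list uchar int vertex_indices\nend_header\n")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(t(m$vertices)), con, size = 4, endian = "little")
  F0 <- t(m$faces) - 1L
  for (i in seq_len(ncol(F0))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(F0[, i]), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Write a mesh as Wavefront OBJ (secondary text format)
#' @param m a [surface_mesh()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_obj <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f",
                     m$vertices[, 1], m$vertices[, 2], m$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", m$faces[, 1], m$faces[, 2], m$faces[, 3]), con)
  invisible(path)
}
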