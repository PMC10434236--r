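#' Write a substrate checkpoint as JSON
#'
#' Documented resumable layout: box, per-bundle metadata, seed, the gamma
#' radius-distribution parameters, and per-fibre control points / radii /
#' full-size target radii.
#'
#' @param s a [substrate()].
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_substrate_json <- function(s, path) {
  dist <- attr(s, "dist")
  obj <- list(
    format = "wmphantom-substrate-v1",
    box = unname(as.matrix(s$box)),
    seed = s$seed,
    bundles = s$bundles,
    dist = if (!is.null(dist)) dist[c("shape", "scale", "trunc", "shrink")],
    fibres = lapply(s$fibres, function(f)
      list(id = f$id, bundle = f$bundle,
           points = unname(f$points), radii = f$radii,
           target_radii = f$target_radii))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a substrate checkpoint written by [write_substrate_json()]
#' @param path JSON path.
#' @return A [substrate()].
#' @export
read_substrate_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "wmphantom-substrate-v1"))
    stop("not a wmphantom substrate checkpoint: ", path)
  fibres <- lapply(seq_len(nrow(obj$fibres)), function(i) {
    f <- obj$fibres[i, ]
    fibre_skeleton(matrix(unlist(f$points[[1]]), ncol = 3),
                   unlist(f$radii), id = f$id, bundle = f$bundle,
                   target_radii = unlist(f$target_radii))
  })
  s <- substrate(fibres, obj$box, obj$bundles, seed = obj$seed)
  if (!is.null(obj$dist))
    attr(s, "dist") <- radius_distribution(obj$dist$shape, obj$dist$scale,
                                           unlist(obj$dist$trunc),
                                           obj$dist$shrink)
  attr(s, "reference") <- s
  s
}

#' Write a voxel ownership grid
#'
#' Uses NIfTI label volumes (via RNifti, one file per field) with a JSON
#' sidecar holding resolution/origin metadata when RNifti is installed;
#' falls back to an RDS file otherwise.
#'
#' @param grid a [voxel_grid()].
#' @param path base path (without extension).
#' @return The main file path, invisibly.
#' @export
write_grid <- function(grid, path) {
  meta <- list(format = "wmphantom-grid-v1", dim = grid$dim, res = grid$res,
               origin = grid$origin, nfib = grid$nfib,
               has_inner = !is.null(grid$inner))
  if (requireNamespace("RNifti", quietly = TRUE)) {
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
    arr <- array(grid$owner, dim = grid$dim)
    RNifti::writeNifti(RNifti::asNifti(arr, pixdim = rep(grid$res, 3)),
                       paste0(path, "_owner.nii.gz"))
    if (!is.null(grid$inner))
      RNifti::writeNifti(RNifti::asNifti(array(grid$inner, dim = grid$dim),
                                         pixdim = rep(grid$res, 3)),
                         paste0(path, "_inner.nii.gz"))
    invisible(paste0(path, ".json"))
  } else {
    saveRDS(grid, paste0(path, ".rds"))
    invisible(paste0(path, ".rds"))
  }
}

#' Read a grid written by [write_grid()]
#' @param path base path used at write time.
#' @return A [voxel_grid()].
#' @export
read_grid <- function(path) {
  if (file.exists(paste0(path, ".json")) &&
      requireNamespace("RNifti", quietly = TRUE)) {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    owner <- as.integer(RNifti::readNifti(paste0(path, "_owner.nii.gz")))
    inner <- NULL
    if (isTRUE(meta$has_inner))
      inner <- as.integer(RNifti::readNifti(paste0(path, "_inner.nii.gz")))
    voxel_grid(owner, integer(length(owner)), meta$dim, meta$res, meta$origin,
               meta$nfib, inner)
  } else if (file.exists(paste0(path, ".rds"))) {
    readRDS(paste0(path, ".rds"))
  } else stop("no grid checkpoint at ", path)
}
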