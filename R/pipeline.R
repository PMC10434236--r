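#' Read and validate a pipeline configuration
#'
#' Configurations are YAML or JSON with the schema below (defaults in
#' parentheses); unknown fields are rejected so typos fail loudly, and
#' missing required fields are reported by name.
#'
#' ```yaml
#' seed: 1                  # required integer; all stage seeds derive from it
#' kind: bundle             # "bundle" or "crossing"
#' bundle:
#'   L: 20                  # face side (um)   [required]
#'   H: 20                  # height (um; default L)
#'   density: 0.6           # target packing fraction [required]
#'   eta: 0                 # mean dispersion (deg)
#'   gamma: {shape: 0.5, scale: 1.1, trunc: [0.5, 4]}
#' crossing:                # only for kind: crossing
#'   theta: 60              # inter-bundle angle (deg)
#'   trim: true             # trim to the central crossing region
#' optimize: {lr: 0.05, max_blocks: 200}
#' growth:
#'   resolution: 0.1        # um/voxel (default min(0.1, r_min*2/5))
#'   seeding: uniform       # or random
#'   cap_factor: 1.0        # 1.5 in the max-density preset
#'   iterations: 1000
#'   stop_fvf: null         # optional FVF target in the analysis region
#' erode:
#'   g_target: 0.7          # or mvf_target
#' mesh: {enabled: true, smooth_iters: 10, decim_fraction: 0.25}
#' metrics: {profile_step: 1.0}
#' ```
#'
#' @param path YAML or JSON file, or a named list already in memory.
#' @return Validated config (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path
  else if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  known <- c("seed", "kind", "bundle", "crossing", "optimize", "growth",
             "erode", "mesh", "metrics", "out_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop("unknown config field(s): ", paste(extra, collapse = ", "))
  req <- function(x, field, where) {
    if (is.null(x))
      stop(sprintf("config validation: required field '%s' is missing in '%s'",
                   field, where))
    x
  }
  req(cfg$seed, "seed", "top level")
  if (!is.numeric(cfg$seed)) stop("config validation: 'seed' must be an integer")
  cfg$kind <- cfg$kind %||% "bundle"
  if (!cfg$kind %in% c("bundle", "crossing"))
    stop("config validation: 'kind' must be \"bundle\" or \"crossing\"")
  b <- req(cfg$bundle, "bundle", "top level")
  req(b$L, "L", "bundle")
  req(b$density, "density", "bundle")
  if (b$density <= 0 || b$density >= 1)
    stop("config validation: 'bundle.density' must be in (0, 1)")
  b$H <- b$H %||% b$L
  b$eta <- b$eta %||% 0
  g <- b$gamma %||% list()
  b$gamma <- list(shape = g$shape %||% 0.5, scale = g$scale %||% 1.1,
                  trunc = unlist(g$trunc %||% c(0.5, 4)))
  cfg$bundle <- b
  if (cfg$kind == "crossing") {
    cr <- req(cfg$crossing, "crossing", "top level")
    cr$theta <- req(cr$theta, "theta", "crossing")
    cr$trim <- cr$trim %||% TRUE
    cfg$crossing <- cr
  }
  o <- cfg$optimize %||% list()
  cfg$optimize <- list(lr = o$lr %||% 0.05,
                       max_blocks = o$max_blocks %||% 200L,
                       polish_budget = o$polish_budget %||% 50L)
  gr <- cfg$growth %||% list()
  cfg$growth <- list(resolution = gr$resolution,
                     seeding = gr$seeding %||% "uniform",
                     cap_factor = gr$cap_factor %||% 1.0,
                     iterations = gr$iterations %||% 1000L,
                     stop_fvf = gr$stop_fvf)
  er <- cfg$erode %||% list()
  cfg$erode <- list(g_target = er$g_target %||% if (is.null(er$mvf_target)) 0.7,
                    mvf_target = er$mvf_target)
  me <- cfg$mesh %||% list()
  cfg$mesh <- list(enabled = me$enabled %||% TRUE,
                   smooth_iters = me$smooth_iters %||% 10L,
                   decim_fraction = me$decim_fraction %||% 0.25)
  mt <- cfg$metrics %||% list()
  cfg$metrics <- list(profile_step = mt$profile_step %||% 1.0)
  structure(cfg, class = "pipeline_config")
}

# One global seed fans out to per-stage substreams so stages can be re-run
# independently; offsets are fixed and documented here.
stage_seed <- function(seed, stage) {
  offsets <- c(init = 0L, optimize = 1L, grow = 2L, erode = 3L, mesh = 4L,
               metrics = 5L)
  (as.integer(seed) + 7919L * offsets[[stage]]) %% 2147483647L
}

#' Run the full substrate-generation pipeline
#'
#' Executes init -> optimize -> (trim) -> grow -> erode -> mesh -> metrics
#' from a validated configuration.  Each stage writes a checkpoint into
#' `out_dir`; a re-run resumes from existing checkpoints (so identical
#' config and seed reproduce identical metrics whether run in one shot or
#' stage by stage).
#'
#' @param config a [read_pipeline_config()] result, or a path/list accepted
#'   by it.
#' @param out_dir artifact directory (created if needed).
#' @param stages subset of stages to run (default all).
#' @param resume reuse existing checkpoints (default TRUE).
#' @param verbose print stage progress.
#' @return Invisibly, a list with the final `substrate`, `grid`, `meshes`
#'   (if enabled), `metrics` and the artifact directory.
#' @export
run_pipeline <- function(config, out_dir = tempfile("wmphantom_"),
                         stages = c("init", "optimize", "grow", "erode",
                                    "mesh", "metrics"),
                         resume = TRUE, verbose = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  ck <- function(name) file.path(out_dir, name)
  dist <- radius_distribution(cfg$bundle$gamma$shape, cfg$bundle$gamma$scale,
                              cfg$bundle$gamma$trunc)

  # ---- init
  s <- NULL
  if (resume && file.exists(ck("substrate_init.json"))) {
    s <- read_substrate_json(ck("substrate_init.json"))
    say("init: resumed from checkpoint")
  } else if ("init" %in% stages) {
    bs <- bundle_spec(cfg$bundle$L, cfg$bundle$H, cfg$bundle$density,
                      cfg$bundle$eta, dist, stage_seed(cfg$seed, "init"))
    s <- if (cfg$kind == "crossing")
      init_crossing(crossing_spec(bs, bs, cfg$crossing$theta))
    else init_bundle(bs)
    write_substrate_json(s, ck("substrate_init.json"))
    init_meta <- list(n_fibres = length(s$fibres),
                      shrink = s$bundles$shrink,
                      initial_density = min(cfg$bundle$density, 0.75))
    jsonlite::write_json(init_meta, ck("init_meta.json"), auto_unbox = TRUE, digits = NA)
    say("init: %d fibres", length(s$fibres))
  }

  # ---- optimize (+ trim for crossings)
  if (resume && file.exists(ck("substrate_opt.json"))) {
    s <- read_substrate_json(ck("substrate_opt.json"))
    say("optimize: resumed")
  } else if ("optimize" %in% stages) {
    if (is.null(s)) stop("stage 'optimize' needs the init checkpoint")
    set.seed(stage_seed(cfg$seed, "optimize"))
    s <- optimize_substrate(
      s, schedule = optimizer_schedule(lr = cfg$optimize$lr,
                                       max_blocks = cfg$optimize$max_blocks,
                                       polish_budget = cfg$optimize$polish_budget),
      log_file = ck("optimize_log.ndjson"), verbose = verbose)
    if (cfg$kind == "crossing" && isTRUE(cfg$crossing$trim))
      s <- trim_crossing(s)
    write_substrate_json(s, ck("substrate_opt.json"))
    say("optimize: overlap-free (%d fibres retained)", length(s$fibres))
  }

  # ---- grow + erode
  grid <- NULL
  if (resume && file.exists(ck("grid.json")) || resume && file.exists(ck("grid.rds"))) {
    grid <- read_grid(ck("grid"))
    say("grow: resumed")
  } else if ("grow" %in% stages || "erode" %in% stages) {
    if (is.null(s)) stop("stage 'grow' needs the optimize checkpoint")
    grid <- rasterize_capsules(s, cfg$growth$resolution)
    pol <- growth_policy(cfg$growth$seeding, cfg$growth$iterations,
                         cfg$growth$cap_factor,
                         seed = stage_seed(cfg$seed, "grow"))
    grid <- grow_fibres(grid, s, pol, stop_fvf = cfg$growth$stop_fvf)
    if ("erode" %in% stages) {
      set.seed(stage_seed(cfg$seed, "erode"))
      grid <- erode_inner(grid, s, g_target = cfg$erode$g_target,
                          mvf_target = cfg$erode$mvf_target)
    }
    write_grid(grid, ck("grid"))
    say("grow: FVF %.1f%%", 100 * volume_fractions(grid)[["FVF"]])
  }

  # ---- mesh
  meshes <- NULL
  if (cfg$mesh$enabled && "mesh" %in% stages && !is.null(grid)) {
    set.seed(stage_seed(cfg$seed, "mesh"))
    mesh_dir <- ck("meshes")
    dir.create(mesh_dir, showWarnings = FALSE)
    meshes <- fibre_meshes(grid, "outer",
                           smooth_iters = cfg$mesh$smooth_iters,
                           decim_fraction = cfg$mesh$decim_fraction)
    manifest <- list()
    for (nm in names(meshes)) {
      p <- file.path(mesh_dir, paste0(nm, "_outer.ply"))
      write_ply(meshes[[nm]], p)
      manifest[[nm]] <- list(fibre_id = meshes[[nm]]$fibre_id, kind = "outer",
                             path = p, volume = mesh_volume(meshes[[nm]]))
    }
    if (!is.null(grid$inner)) {
      inner_meshes <- fibre_meshes(grid, "inner",
                                   smooth_iters = cfg$mesh$smooth_iters,
                                   decim_fraction = cfg$mesh$decim_fraction)
      for (nm in names(inner_meshes)) {
        p <- file.path(mesh_dir, paste0(nm, "_inner.ply"))
        write_ply(inner_meshes[[nm]], p)
        manifest[[paste0(nm, "_inner")]] <-
          list(fibre_id = inner_meshes[[nm]]$fibre_id, kind = "inner",
               path = p, volume = mesh_volume(inner_meshes[[nm]]))
      }
    }
    jsonlite::write_json(manifest, ck("mesh_manifest.json"), auto_unbox = TRUE, digits = NA)
    say("mesh: %d fibre meshes", length(meshes))
  }

  # ---- metrics
  metrics <- NULL
  if ("metrics" %in% stages && !is.null(grid)) {
    if (is.null(s)) stop("stage 'metrics' needs a substrate checkpoint")
    metrics <- substrate_metrics(grid, s, meshes,
                                 profile_step = cfg$metrics$profile_step)
    out <- metrics
    out$profiles <- NULL
    jsonlite::write_json(out, ck("metrics.json"), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
    if (!is.null(metrics$profiles))
      write_profiles_csv(metrics$profiles, ck("profiles.csv"))
    say("metrics: FVF %.1f%%, g %.3f", 100 * metrics$FVF, metrics$g_ratio)
  }
  invisible(list(substrate = s, grid = grid, meshes = meshes,
                 metrics = metrics, out_dir = out_dir))
}

#' Deterministic fixtures used across the test suite
#'
#' @param name one of `"two-capsule-overlap"` (the parallel unit-capsule
#'   configuration with overlap depth D = 0.5), `"four-fibre-toy"` (a small
#'   overlapping substrate for gradient checks), `"bundle-20"` (a packed
#'   ~20-fibre bundle), `"crossing-60"` (two ~10-fibre bundles at 60
#'   degrees), `"digital-ball-20"` (a radius-20-voxel ball mask) or
#'   `"elliptic-cylinder"` (a 2 x 0.5 um semi-axis cylinder mask with its
#'   skeleton).
#' @return Fixture object (type depends on the fixture; see Details).
#' @export
make_fixture <- function(name) {
  switch(
    name,
    "two-capsule-overlap" = list(
      a = capsule(c(0, 0, 0), c(1, 0, 0), 1, 1),
      b = capsule(c(0, 1, 0), c(1, 1, 0), 1, 1),
      D = 0.5, cost = 0.25),
    "four-fibre-toy" = {
      # four parallel fibres pinned closer than their diameters: guaranteed
      # overlaps, non-degenerate closest approaches after a deterministic bend
      mk <- function(x, y, id) {
        pts <- cbind(x + c(0, 0.15, -0.1, 0.05, 0), y + c(0, -0.05, 0.1, 0, 0),
                     seq(0, 8, length.out = 5))
        fibre_skeleton(pts, rep(0.8, 5), id = id)
      }
      s <- substrate(list(mk(3.0, 3.0, 1L), mk(4.2, 3.1, 2L),
                          mk(3.1, 4.2, 3L), mk(4.2, 4.2, 4L)),
                     rbind(c(0, 0, 0), c(7.2, 7.2, 8)))
      attr(s, "reference") <- s
      s
    },
    "bundle-20" = init_bundle(bundle_spec(L = 8, H = 8, density = 0.5,
                                          eta = 0, seed = 7L)),
    "crossing-60" = {
      narrow <- radius_distribution(shape = 60, scale = 1 / 60,
                                    trunc = c(0.8, 1.2))
      bs <- bundle_spec(L = 6, H = 16, density = 0.22, eta = 0,
                        dist = narrow, seed = 11L)
      init_crossing(crossing_spec(bs, bs, theta = 60))
    },
    "digital-ball-20" = {
      n <- 45L
      cc <- (n + 1) / 2
      g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
      mask <- array((g$x - cc)^2 + (g$y - cc)^2 + (g$z - cc)^2 <= 20^2,
                    dim = c(n, n, n))
      list(mask = mask, radius_voxels = 20, centre = rep(cc, 3))
    },
    "elliptic-cylinder" = {
      res <- 0.05
      a <- 2; b <- 0.5; len <- 10
      nx <- as.integer(2 * (a + 0.3) / res)
      ny <- as.integer(2 * (b + 0.3) / res)
      nz <- as.integer((len + 0.6) / res)
      orig <- c(-(a + 0.3), -(b + 0.3), -0.3)
      xs <- orig[1] + (seq_len(nx) - 0.5) * res
      ys <- orig[2] + (seq_len(ny) - 0.5) * res
      zs <- orig[3] + (seq_len(nz) - 0.5) * res
      inside2d <- outer(xs^2 / a^2, ys^2 / b^2, "+") <= 1
      inz <- zs >= 0 & zs <= len
      mask <- array(FALSE, dim = c(nx, ny, nz))
      for (k in which(inz)) mask[, , k] <- inside2d
      skel <- fibre_skeleton(cbind(0, 0, seq(0, len, by = 1)),
                             rep(sqrt(a * b), 11))
      list(mask = mask, res = res, origin = orig, skeleton = skel,
           equivalent_radius = sqrt(a * b))
    },
    stop("unknown fixture: ", name)
  )
}

# ---- presets used by the acceptance analyses ------------------------------

#' Max-density single bundle, end-to-end
#'
#' Builds a single straight bundle (zero dispersion) with gamma-sampled
#' radii, runs the joint optimization to the overlap-free state, and applies
#' fibre radial growth with the max-density settings (radius cap factor 1.5,
#' growth until no voxel can be claimed) so fibres fill the pockets between
#' cylindrical shapes.  Returns the voxel-based FVF over the central 80%
#' analysis region.
#'
#' @param side box side (um).
#' @param density initial packing density target.
#' @param resolution voxel edge (um).
#' @param seed integer seed.
#' @return List with `fvf` (fraction), `substrate`, `grid`.
#' @export
preset_max_density_bundle <- function(side = 50, density = 0.70,
                                      resolution = 0.1, seed = 1L) {
  bs <- bundle_spec(L = side, H = side, density = density, eta = 0,
                    seed = stage_seed(seed, "init"))
  s <- init_bundle(bs)
  s <- optimize_substrate(s)
  grid <- rasterize_capsules(s, resolution)
  pol <- growth_policy("uniform", iterations = 10000L, cap_factor = 1.5,
                       seed = stage_seed(seed, "grow"))
  grid <- grow_fibres(grid, s, pol)
  fvf <- volume_fractions(grid)[["FVF"]]
  list(fvf = fvf, substrate = s, grid = grid)
}

#' Single bundle tuned to target volume fractions
#'
#' Grows a straight bundle until the fibre volume fraction in the central
#' analysis region reaches the target (stopping voxel-exactly mid-layer),
#' then erodes each fibre toward the erosion depth that realises the target
#' myelin fraction.  Targets are fractions (e.g. `c(avf = 0.25, mvf = 0.35,
#' fvf = 0.60)`).
#'
#' @param targets named fractions `avf`, `mvf`, `fvf` (avf + mvf = fvf).
#' @param side box side (um).
#' @param resolution voxel edge (um).
#' @param seed integer seed.
#' @return List with `achieved` (named AVF/MVF/FVF fractions), `targets`,
#'   `max_abs_dev_pp` (max |achieved - target| in percentage points),
#'   `grid`, `substrate`.
#' @export
preset_targeted_bundle <- function(targets = c(avf = 0.25, mvf = 0.35, fvf = 0.60),
                                   side = 50, resolution = 0.1, seed = 1L) {
  if (abs(targets[["avf"]] + targets[["mvf"]] - targets[["fvf"]]) > 1e-9)
    stop("targets must satisfy avf + mvf = fvf")
  init_density <- max(0.2, targets[["fvf"]] - 0.05)
  bs <- bundle_spec(L = side, H = side, density = init_density, eta = 0,
                    seed = stage_seed(seed, "init"))
  s <- init_bundle(bs)
  s <- optimize_substrate(s)
  grid <- rasterize_capsules(s, resolution)
  pol <- growth_policy("uniform", iterations = 10000L, cap_factor = 1.5,
                       seed = stage_seed(seed, "grow"))
  grid <- grow_fibres(grid, s, pol, stop_fvf = targets[["fvf"]])
  grid <- erode_inner(grid, s, g_target = NULL, mvf_target = targets[["mvf"]])
  vf <- volume_fractions(grid)
  achieved <- c(avf = vf[["AVF"]], mvf = vf[["MVF"]], fvf = vf[["FVF"]])
  dev <- 100 * max(abs(achieved - targets[c("avf", "mvf", "fvf")]))
  list(achieved = achieved, targets = targets, max_abs_dev_pp = dev,
       grid = grid, substrate = s)
}

#' Dense toy bundle with a fixed target outer diameter
#'
#' Packs a handful of equal-calibre fibres (target outer diameter
#' `diameter` um), initialises them at shrunken radii, regrows them to the
#' radius cap, meshes each fibre and measures the mean equivalent outer
#' diameter by the orthogonal cross-section procedure at 1 um steps.
#'
#' @param diameter target outer diameter (um).
#' @param n_fibres number of fibres (3--10).
#' @param seed integer seed.
#' @param resolution voxel edge (um).
#' @return List with `mean_equivalent_diameter` (um), per-fibre means,
#'   `meshes`, `substrate`, `grid`.
#' @export
preset_diameter_toy <- function(diameter = 1.5, n_fibres = 7L, seed = 1L,
                                resolution = 0.05) {
  r_target <- diameter / 2
  # face sized for a dense arrangement (~60% packing)
  L <- sqrt(n_fibres * pi * r_target^2 / 0.6)
  H <- 12
  set.seed(stage_seed(seed, "init"))
  centres <- pack_disks_2d(L, rep(r_target, n_fibres))
  shrink <- 2 / 3
  fibres <- lapply(seq_len(n_fibres), function(i) {
    pts <- subdivide_chord(c(centres[i, ], 0), c(centres[i, ], H),
                           r_target * shrink)
    fibre_skeleton(pts, rep(r_target * shrink, nrow(pts)), id = i,
                   target_radii = rep(r_target, nrow(pts)))
  })
  s <- substrate(fibres, rbind(c(0, 0, 0), c(L, L, H)))
  attr(s, "reference") <- s
  grid <- rasterize_capsules(s, resolution)
  pol <- growth_policy("uniform", iterations = 1000L, cap_factor = 1.0,
                       seed = stage_seed(seed, "grow"))
  grid <- grow_fibres(grid, s, pol)
  meshes <- fibre_meshes(grid, "outer", smooth_iters = 5L, decim_fraction = 0.5)
  prof <- profile_all_fibres(meshes, s, step = 1)
  list(mean_equivalent_diameter = 2 * mean(prof$mean_radii, na.rm = TRUE),
       per_fibre_mean_radii = prof$mean_radii,
       meshes = meshes, substrate = s, grid = grid)
}
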