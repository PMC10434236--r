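#' Candidate capsule pairs from the fixed-radius-cell broad phase
#'
#' Hashes capsule midpoints into a uniform grid whose cell size is at least
#' twice the largest capsule half-extent plus radius, so that querying the
#' 27-cell neighbourhood can never miss an overlapping pair.  Pairs of
#' capsules belonging to the same fibre are never returned (intra-fibre
#' contact is governed by the curvature penalty, not by the overlap cost),
#' and each unordered pair appears once.
#'
#' @param s a [substrate()].
#' @return Integer matrix (K x 2) of 0-based capsule indices; capsule `i`
#'   spans control points `capA[i]` and `capA[i]+1` of the flattened
#'   substrate (see attribute `capsules`).
#' @export
candidate_pairs <- function(s) {
  arr <- substrate_arrays(s)
  out <- cpp_candidate_pairs(arr$P, arr$R, arr$capA, arr$capF)
  attr(out, "capsules") <- data.frame(first_point = arr$capA, fibre = arr$capF + 1L)
  out
}

#' Count overlapping capsule pairs
#'
#' Number of cross-fibre capsule pairs with positive overlap depth `D`
#' (interpenetrating closest spheres), computed over the complete candidate
#' set of the broad phase, together with the maximum depth.
#'
#' @param s a [substrate()].
#' @return List with `count` and `max_D` (`-Inf` when no pair is close).
#' @export
overlap_count <- function(s) {
  arr <- substrate_arrays(s)
  ov <- cpp_overlap_total(arr$P, arr$R, arr$capA, arr$capF, NULL, FALSE)
  list(count = ov$overlap_count,
       max_D = if (is.na(ov$max_D)) -Inf else ov$max_D)
}

#' Optimization schedule for [optimize_substrate()]
#'
#' @param lr Adagrad base learning rate (um scale).
#' @param block_overlap iterations per overlap-only block.
#' @param block_polish iterations per regularizer-polish block.
#' @param max_blocks maximum number of alternating blocks before declaring
#'   failure to remove overlaps.
#' @param polish_budget polish iterations run after the substrate is
#'   overlap-free.
#' @param radius_bounds allowed radii range as fractions of the target radii
#'   (radii may shrink locally during disentangling; radial growth restores
#'   them later).
#' @param margin safety margin: the overlap phase descends on the cost of
#'   radii inflated by this fraction, so its gradient stays non-vanishing
#'   until the true overlaps (which terminate the phase) have strictly
#'   cleared.  Without it the quadratic penalty approaches the zero-overlap
#'   boundary only asymptotically.
#' @param epsilon Adagrad accumulator offset.
#' @return A list of schedule parameters.
#' @export
optimizer_schedule <- function(lr = 0.05, block_overlap = 50L,
                               block_polish = 10L, max_blocks = 200L,
                               polish_budget = 50L,
                               radius_bounds = c(0.4, 1.0),
                               margin = 0.04, epsilon = 1e-8) {
  list(lr = lr, block_overlap = as.integer(block_overlap),
       block_polish = as.integer(block_polish),
       max_blocks = as.integer(max_blocks),
       polish_budget = as.integer(polish_budget),
       radius_bounds = radius_bounds, margin = margin, epsilon = epsilon)
}

#' Joint fibre optimization: remove all capsule overlaps
#'
#' Alternates Adagrad gradient-descent blocks on the overlap cost alone with
#' short polish blocks on the weighted regularizers (curvature, length,
#' radii change, compactness), until no cross-fibre capsule pair
#' interpenetrates; the run then finishes with a fixed polish budget.  Fibre
#' endpoints on the cuboid faces are held fixed; interior control points and
#' all radii are free (radii are clamped to a fraction band around their
#' targets).  Any polish step that re-introduces an overlap, or increases
#' the summed regularizer cost, is rolled back with up to five step
#' halvings, so the output is guaranteed overlap-free and the regularizer
#' cost is non-increasing across accepted polish steps.
#'
#' @param s an initialised [substrate()] (may contain overlaps).
#' @param weights a [cost_weights()]; the overlap weight must strictly
#'   dominate the others.
#' @param schedule an [optimizer_schedule()].
#' @param log_file optional path; iteration records are appended as
#'   line-delimited JSON.
#' @param verbose print progress every block.
#' @return The overlap-free [substrate()], with the iteration log as
#'   attribute `log` (data frame: iteration, phase, overlap count, max depth,
#'   cost terms).  Errors if overlaps remain after `max_blocks` blocks,
#'   reporting the residual overlap count and maximum depth.
#' @export
optimize_substrate <- function(s, weights = cost_weights(),
                               schedule = optimizer_schedule(),
                               log_file = NULL, verbose = FALSE) {
  stopifnot(inherits(s, "substrate"))
  if (weights$overlap <= max(weights$curvature, weights$length,
                             weights$radii_change, weights$compactness))
    stop("the overlap weight must strictly dominate the regularizer weights")
  arr <- substrate_arrays(s)
  reference <- attr(s, "reference") %||% s
  P <- arr$P; R <- arr$R
  lo <- s$box[1, ]; hi <- s$box[2, ]
  rlo <- schedule$radius_bounds[1] * arr$Rt
  rhi <- schedule$radius_bounds[2] * arr$Rt
  accP <- matrix(0, nrow(P), 3); accR <- numeric(length(R))
  eps <- schedule$epsilon
  logs <- list()
  it <- 0L
  ov_weights <- cost_weights(overlap = weights$overlap, curvature = 0,
                             length = 0, radii_change = 0, compactness = 0)

  eval_state <- function(P, R, w) {
    s2 <- substrate_from_arrays(s, arr, P, R)
    total_cost_and_gradient(s2, w, pairs = NULL, reference = reference)
  }
  log_row <- function(phase, st) {
    row <- data.frame(iteration = it, phase = phase,
                      overlap_count = st$overlap_count,
                      max_D = if (is.finite(st$max_D)) st$max_D else NA_real_,
                      overlap = st$terms[["overlap"]],
                      curvature = st$terms[["curvature"]],
                      length = st$terms[["length"]],
                      radii_change = st$terms[["radii_change"]],
                      compactness = st$terms[["compactness"]])
    logs[[length(logs) + 1L]] <<- row
    if (!is.null(log_file))
      cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE), "\n",
          file = log_file, append = TRUE)
  }
  adagrad_step <- function(P, R, st, lr_scale = 1) {
    g <- st$grad_points; gr <- st$grad_radii
    accP <<- accP + g^2; accR <<- accR + gr^2
    P <- P - schedule$lr * lr_scale * g / sqrt(accP + eps)
    R <- R - schedule$lr * lr_scale * gr / sqrt(accR + eps)
    P[!arr$fixed, 1] <- pmin(pmax(P[!arr$fixed, 1], lo[1]), hi[1])
    P[!arr$fixed, 2] <- pmin(pmax(P[!arr$fixed, 2], lo[2]), hi[2])
    P[!arr$fixed, 3] <- pmin(pmax(P[!arr$fixed, 3], lo[3]), hi[3])
    R <- pmin(pmax(R, rlo), rhi)
    list(P = P, R = R)
  }

  st <- eval_state(P, R, weights)
  log_row("init", st)
  free <- st$overlap_count == 0L
  block <- 0L
  marg <- 1 + schedule$margin
  while (!free && block < schedule$max_blocks) {
    block <- block + 1L
    for (k in seq_len(schedule$block_overlap)) {
      it <- it + 1L
      true_ov <- cpp_overlap_total(P, R, arr$capA, arr$capF, NULL, FALSE)
      if (true_ov$overlap_count == 0L) { free <- TRUE; break }
      # descend on the margin-inflated overlap cost (gradient stays alive
      # while true overlaps persist)
      ov <- cpp_overlap_total(P, R * marg, arr$capA, arr$capF, NULL, TRUE)
      gP_ov <- weights$overlap * ov$grad_points
      gP_ov[arr$fixed, ] <- 0
      sto <- list(grad_points = gP_ov,
                  grad_radii = weights$overlap * marg * ov$grad_radii)
      stp <- adagrad_step(P, R, sto)
      P <- stp$P; R <- stp$R
    }
    st <- eval_state(P, R, weights)
    log_row("overlap", st)
    if (st$overlap_count == 0L) free <- TRUE
    if (verbose)
      message(sprintf("block %d: %d overlaps, max D %.3g", block,
                      st$overlap_count, st$max_D))
    if (!free && schedule$block_polish > 0) {
      res <- polish_steps(P, R, schedule$block_polish, weights, eval_state,
                          adagrad_step, require_free = FALSE)
      P <- res$P; R <- res$R
    }
  }
  st <- eval_state(P, R, weights)
  if (st$overlap_count > 0L)
    stop(sprintf(
      "joint optimization failed: %d overlapping capsule pairs remain (max depth D = %.4g) after %d blocks",
      st$overlap_count, st$max_D, block))
  # final polish under the no-overlap guarantee
  for (k in seq_len(schedule$polish_budget)) {
    it <- it + 1L
    st <- eval_state(P, R, weights)
    reg_before <- sum(st$terms[2:5] * unlist(weights[2:5]))
    ok <- FALSE
    scale <- 1
    accP_s <- accP; accR_s <- accR
    for (h in 1:5) {
      stp <- adagrad_step(P, R, st, lr_scale = scale)
      chk <- eval_state(stp$P, stp$R, weights)
      reg_after <- sum(chk$terms[2:5] * unlist(weights[2:5]))
      if (chk$overlap_count == 0L && reg_after <= reg_before + 1e-12) {
        P <- stp$P; R <- stp$R; ok <- TRUE
        break
      }
      accP <- accP_s; accR <- accR_s   # roll back accumulator too
      scale <- scale / 2
    }
    if (!ok) break
  }
  st <- eval_state(P, R, weights)
  log_row("polish", st)
  out <- substrate_from_arrays(s, arr, P, R)
  attr(out, "reference") <- reference
  attr(out, "dist") <- attr(s, "dist")
  attr(out, "log") <- do.call(rbind, logs)
  out
}

# Shared helper: a few guarded polish iterations (used between overlap blocks,
# where overlaps may still exist and only the regularizer decrease is
# enforced).
polish_steps <- function(P, R, n, weights, eval_state, adagrad_step,
                         require_free = TRUE) {
  reg_w <- cost_weights(overlap = weights$overlap, # keep overlap pressure on
                        curvature = weights$curvature,
                        length = weights$length,
                        radii_change = weights$radii_change,
                        compactness = weights$compactness)
  for (k in seq_len(n)) {
    st <- eval_state(P, R, reg_w)
    stp <- adagrad_step(P, R, st)
    chk <- eval_state(stp$P, stp$R, reg_w)
    if (require_free && chk$overlap_count > 0) break
    P <- stp$P; R <- stp$R
  }
  list(P = P, R = R)
}
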