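#' Ground-truth tuning for a switching synthetic population
#'
#' Constructs per-cell encoding axes for a population whose face code switches
#' abruptly: every cell's early face axis points with positive loadings into
#' the first `flip_dims` feature dimensions (the shared face-detection
#' direction) plus small random high-dimensional components; after
#' `switch_time_ms` the face axis negates those low-dimensional loadings
#' (reversal) and gains fresh independent loadings on the next `new_dims`
#' dimensions (emergent tuning). Object axes equal the early axes and never
#' change, so only face stimuli are routed through the switch.
#'
#' All axes are normalized to unit length; response magnitude is carried by
#' the per-cell `gain_hz`.
#'
#' @param K Feature-space dimensionality of the axes.
#' @param n_cells Number of cells.
#' @param flip_dims Number of leading dimensions whose loadings reverse sign
#'   at the switch.
#' @param new_dims Number of dimensions (following the flipped block) on which
#'   the late face axis draws fresh independent loadings.
#' @param new_gain Norm of the fresh (emergent) loading block relative to
#'   the flipped block: values above 1 make the new tuning directions
#'   dominate the late axis, matching the large orthogonal component of late
#'   axes seen in real cells.
#' @param new_loading_decay Geometric decay of the fresh late-axis loading
#'   s.d. across the new dimensions: loadings are allocated in proportion to
#'   the stimulus variance spectrum (efficient coding), so emergent tuning
#'   concentrates on dimensions that still carry stimulus variance. Set to 1
#'   for uniform allocation.
#' @param switch_time_ms Time of the (instantaneous) axis switch, ms after
#'   stimulus onset.
#' @param gain_hz Median response gain in Hz per unit feature projection;
#'   per-cell gains are log-normally jittered around it.
#' @param baseline_hz Median spontaneous firing rate.
#' @param visual_drive_hz Median nonspecific visual onset drive (Hz at kernel
#'   peak): every stimulus, preferred or not, evokes this stimulus-unspecific
#'   response component, so anti-preferred stimuli modulate around a driven
#'   rate rather than silencing the cell.
#' @param object_gain_frac Gain applied to object stimuli as a fraction of
#'   the face gain: face cells devote most of their dynamic range to the face
#'   region of object space, so object responses span a compressed range.
#' @param latency_base_ms,latency_jitter_ms Visual response latency: each cell
#'   gets `latency_base_ms` plus a uniform draw on `[0, latency_jitter_ms]`.
#' @param flip_loading_sd Spread of the positive detection-direction
#'   loadings across cells (loadings are `|N(1, flip_loading_sd)|`); larger
#'   values reproduce the angular dispersion of object axes seen across real
#'   face cells.
#' @param highdim_sd Standard deviation of the small random loadings on
#'   dimensions beyond the flipped block in the early axis (0 gives exactly
#'   low-dimensional early axes).
#' @param noise_model `"poisson"` (trial spike counts) or `"gaussian"`
#'   (additive rate noise with s.d. `noise_sd` per 1-ms bin and trial).
#' @param noise_sd Gaussian noise s.d. (ignored for Poisson).
#' @param late_offset_frac Operating point of the post-switch face code: the
#'   late drive is `<late_axis, f - mean_face> + late_offset_frac *
#'   <early_axis, mean_face>`, i.e. the late code is referenced to the mean
#'   face (norm-based face-space coding) while retaining this fraction of the
#'   detection-phase mean drive, so post-switch face responses are sparser
#'   but still measurable.
#' @param seed Integer seed.
#'
#' @return A `ground_truth` object: matrices `early_axis`, `late_face_axis`,
#'   `object_axis` (cells x K, unit rows), per-cell `gain_hz`, `latency_ms`,
#'   `baseline_hz`, plus the scalar switch/noise parameters.
#' @export
make_switching_truth <- function(K = 60, n_cells = 100, flip_dims = 5,
                                 new_dims = K - flip_dims,
                                 new_gain = 2.5, new_loading_decay = 1,
                                 switch_time_ms = 110,
                                 gain_hz = 40, baseline_hz = 5,
                                 visual_drive_hz = 12, object_gain_frac = 0.4,
                                 latency_base_ms = 50, latency_jitter_ms = 20,
                                 flip_loading_sd = 0.5, highdim_sd = 0.25,
                                 noise_model = c("poisson", "gaussian"),
                                 noise_sd = 30, late_offset_frac = 0,
                                 seed = 1) {
  noise_model <- match.arg(noise_model)
  if (flip_dims == 0 && new_dims == 0) {
    abort("flip_dims = 0 and new_dims = 0 is degenerate; use make_no_switch_truth().")
  }
  stopifnot(flip_dims + new_dims <= K, flip_dims >= 0, new_dims >= 0)
  with_seed(seed, {
    early <- matrix(0, n_cells, K)
    late <- matrix(0, n_cells, K)
    for (j in seq_len(n_cells)) {
      e <- numeric(K)
      e[seq_len(flip_dims)] <- abs(rnorm(flip_dims, mean = 1, sd = flip_loading_sd))
      if (K > flip_dims && highdim_sd > 0) {
        e[(flip_dims + 1):K] <- rnorm(K - flip_dims, 0, highdim_sd)
      }
      l <- e
      if (flip_dims > 0) l[seq_len(flip_dims)] <- -e[seq_len(flip_dims)]
      if (new_dims > 0) {
        idx <- (flip_dims + 1):(flip_dims + new_dims)
        block_norm <- sqrt(sum(e[seq_len(flip_dims)]^2))
        if (block_norm == 0) block_norm <- 1
        prof <- new_loading_decay^(idx - 1)
        prof <- prof / sqrt(sum(prof^2))
        l[idx] <- rnorm(new_dims, 0, new_gain * block_norm * prof)
      }
      early[j, ] <- e / sqrt(sum(e^2))
      late[j, ] <- l / sqrt(sum(l^2))
    }
    gains <- gain_hz * exp(rnorm(n_cells, 0, 0.2))
    lats <- latency_base_ms + runif(n_cells, 0, latency_jitter_ms)
    base <- baseline_hz * exp(rnorm(n_cells, 0, 0.2))
    visual <- visual_drive_hz * exp(rnorm(n_cells, 0, 0.2))
    structure(
      list(early_axis = early, late_face_axis = late, object_axis = early,
           switch_time_ms = switch_time_ms, gain_hz = gains,
           visual_drive_hz = visual, object_gain_frac = object_gain_frac,
           latency_ms = lats, baseline_hz = base,
           noise_model = noise_model, noise_sd = noise_sd,
           late_offset_frac = late_offset_frac,
           flip_dims = flip_dims, new_dims = new_dims, seed = seed),
      class = "ground_truth"
    )
  })
}

#' Ground truth for a matched no-switch control population
#'
#' Identical construction to [make_switching_truth()] except the late face
#' axis equals the early axis: the population encodes a single fixed axis per
#' cell, so no downstream detector should report reversal.
#'
#' @inheritParams make_switching_truth
#' @export
make_no_switch_truth <- function(K = 60, n_cells = 100, flip_dims = 5,
                                 gain_hz = 40, baseline_hz = 5,
                                 visual_drive_hz = 12, object_gain_frac = 0.4,
                                 latency_base_ms = 50, latency_jitter_ms = 20,
                                 flip_loading_sd = 0.5, highdim_sd = 0.25,
                                 noise_model = c("poisson", "gaussian"),
                                 noise_sd = 30, seed = 1) {
  tr <- make_switching_truth(K = K, n_cells = n_cells, flip_dims = flip_dims,
                             new_dims = min(1L, K - flip_dims),
                             gain_hz = gain_hz, baseline_hz = baseline_hz,
                             visual_drive_hz = visual_drive_hz,
                             object_gain_frac = object_gain_frac,
                             latency_base_ms = latency_base_ms,
                             latency_jitter_ms = latency_jitter_ms,
                             flip_loading_sd = flip_loading_sd,
                             highdim_sd = highdim_sd,
                             noise_model = noise_model, noise_sd = noise_sd,
                             seed = seed)
  tr$late_face_axis <- tr$early_axis
  # a full mean-drive offset makes the post-switch drive identical to the
  # pre-switch drive, so the control population is exactly stationary
  tr$late_offset_frac <- 1
  tr$flip_dims <- 0L
  tr$new_dims <- 0L
  tr
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d cells, K = %d, switch at %g ms (%d flipped + %d new dims), %s noise\n",
    nrow(x$early_axis), ncol(x$early_axis), x$switch_time_ms,
    x$flip_dims, x$new_dims, x$noise_model))
  invisible(x)
}

#' Map ground-truth axes into a fitted feature space
#'
#' Ground-truth axes act on raw embedding coordinates; fitted preferred axes
#' live in the normalized PCA coordinates of a [fit_feature_space()] space.
#' For a response `r = <a, x>` with features `f = (x - mean) C / s`, the
#' implied feature-space axis is `w = diag(s) C' a`. Use this to compare
#' recovered axes with generating ones.
#'
#' @param truth A `ground_truth`.
#' @param space A `feature_space` fitted on the same embeddings.
#' @param which Which axis set: `"early"`, `"late"` or `"object"`.
#' @return cells x K matrix of axes in feature coordinates.
#' @export
truth_axes_in_space <- function(truth, space,
                                which = c("early", "late", "object")) {
  which <- match.arg(which)
  A <- switch(which, early = truth$early_axis, late = truth$late_face_axis,
              object = truth$object_axis)
  D <- nrow(space$components)
  if (ncol(A) < D) A <- cbind(A, matrix(0, nrow(A), D - ncol(A)))
  t(diag(space$scale, length(space$scale)) %*% t(space$components) %*% t(A))
}
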