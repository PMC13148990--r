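#' Temporal response kernel
#'
#' Difference-of-exponentials firing-rate kernel gated on stimulus onset:
#' `k(t) = exp(-t/decay) - exp(-t/rise)` for `t >= 0` (0 before), normalized
#' to peak 1. With the defaults (rise 10 ms, decay 40 ms) it produces the
#' transient-then-sustained shape typical of inferotemporal responses.
#'
#' @param t Time in ms (vector), relative to response onset.
#' @param rise_ms,decay_ms Kernel time constants.
#' @return Kernel values in `[0, 1]`.
#' @export
resp_kernel <- function(t, rise_ms = 10, decay_ms = 40) {
  stopifnot(decay_ms > rise_ms)
  t_peak <- rise_ms * decay_ms / (decay_ms - rise_ms) * log(decay_ms / rise_ms)
  peak <- exp(-t_peak / decay_ms) - exp(-t_peak / rise_ms)
  k <- ifelse(t >= 0, (exp(-t / decay_ms) - exp(-t / rise_ms)) / peak, 0)
  pmax(k, 0)
}

new_response_tensor <- function(rates, time_ms, n_repeats, category, ids,
                                cell_ids = sprintf("cell_%03d", seq_len(dim(rates)[1]))) {
  structure(
    list(rates = rates, time_ms = time_ms, n_repeats = n_repeats,
         category = category, ids = ids, cell_ids = cell_ids),
    class = "response_tensor"
  )
}

#' Construct a response tensor from given rates
#'
#' Low-level constructor wrapping a cells x stimuli x time firing-rate array
#' (Hz, 1-ms bins) with its metadata, for externally supplied or hand-built
#' data.
#'
#' @param rates cells x stimuli x T array.
#' @param time_ms Length-T vector of bin times (strictly increasing, 1-ms
#'   spacing), relative to stimulus onset.
#' @param category Per-stimulus labels in `{face, object}`.
#' @param ids Stimulus identifiers.
#' @param n_repeats Trials averaged into each rate.
#' @param cell_ids Optional cell identifiers.
#' @return A `response_tensor`.
#' @export
response_tensor <- function(rates, time_ms, category,
                            ids = sprintf("stim_%04d", seq_len(dim(rates)[2])),
                            n_repeats = 1,
                            cell_ids = sprintf("cell_%03d", seq_len(dim(rates)[1]))) {
  rates <- as.array(rates)
  if (length(dim(rates)) != 3) abort("rates must be a 3-D array")
  if (length(time_ms) != dim(rates)[3]) abort("time_ms length mismatch")
  if (any(diff(time_ms) != 1)) abort("time_ms must be 1-ms spaced")
  if (length(category) != dim(rates)[2]) abort("category length mismatch")
  new_response_tensor(rates, time_ms, n_repeats,
                      factor(as.character(category),
                             levels = c("face", "object")),
                      ids, cell_ids)
}

#' @export
print.response_tensor <- function(x, ...) {
  d <- dim(x$rates)
  cat(sprintf("<response_tensor> %d cells x %d stimuli x %d ms bins [%d..%d ms], %d repeats\n",
              d[1], d[2], d[3], min(x$time_ms), max(x$time_ms), x$n_repeats))
  invisible(x)
}

apply_rate_noise <- function(mean_rate, noise_model, noise_sd, n_repeats,
                             dt_s = 0.001) {
  if (noise_model == "poisson") {
    # sum of n_repeats Poisson trials has intensity n_repeats * lambda;
    # rectified mean used as intensity
    lam <- pmax(mean_rate, 0) * dt_s * n_repeats
    r <- rpois(length(lam), lam) / (n_repeats * dt_s)
  } else if (noise_model == "gaussian") {
    # per-trial per-bin additive noise, averaged over repeats, then rectified
    r <- pmax(mean_rate + rnorm(length(mean_rate),
                                sd = noise_sd / sqrt(n_repeats)), 0)
  } else if (noise_model == "none") {
    r <- mean_rate
  } else {
    abort(sprintf("unknown noise model '%s'", noise_model))
  }
  array(r, dim = dim(mean_rate))
}

#' Simulate a neural population from ground-truth axes
#'
#' Generates a cells x stimuli x time firing-rate tensor (Hz, 1-ms bins). For
#' each cell the expected rate is
#' `baseline + gain * <axis(t), f> * kernel(t - latency)`, rectified at 0,
#' where `f` is the stimulus embedding restricted to the first K coordinates.
#' Face stimuli use the early axis before `switch_time_ms` and the late face
#' axis from then on (optionally crossfaded); object stimuli use the object
#' axis throughout. Trial noise follows the truth's noise model and the
#' `n_repeats` trials are averaged into the returned rates.
#'
#' @param stimuli A [make_stimulus_set()] stimulus set.
#' @param truth A [make_switching_truth()] / [make_no_switch_truth()] object.
#' @param time_ms Integer vector of 1-ms bin times relative to stimulus onset.
#' @param n_repeats Trials per cell x stimulus (>= 1).
#' @param crossfade_ms If > 0, the switch is a linear crossfade of this
#'   duration centred on `switch_time_ms` instead of an instantaneous jump.
#' @param noise_override Optional: `"none"`, `"poisson"` or `"gaussian"`,
#'   overriding the truth's noise model (e.g. for noiseless checks).
#' @param seed Seed for the trial noise; defaults to `truth$seed`.
#' @return A `response_tensor`.
#' @export
simulate_population <- function(stimuli, truth, time_ms = -50:299,
                                n_repeats = 10, crossfade_ms = 0,
                                noise_override = NULL, seed = truth$seed) {
  stopifnot(inherits(stimuli, "stimulus_set"), inherits(truth, "ground_truth"))
  if (n_repeats < 1) abort("n_repeats must be >= 1")
  if (any(diff(time_ms) != 1)) abort("time_ms must be 1-ms spaced")
  K <- ncol(truth$early_axis)
  D <- ncol(stimuli$embeddings)
  if (K > D) abort("truth axis dimension K exceeds embedding dimension D")
  noise_model <- if (is.null(noise_override)) truth$noise_model else noise_override

  f <- stimuli$embeddings[, seq_len(K), drop = FALSE]
  is_face <- stimuli$category == "face"
  n_cells <- nrow(truth$early_axis)
  n_stim <- nrow(f)
  Tn <- length(time_ms)

  # stimulus x cell projections under the pre- and post-switch codes; the
  # post-switch face code is referenced to the mean face (see
  # make_switching_truth, late_offset_frac)
  ogf <- if (is.null(truth$object_gain_frac)) 1 else truth$object_gain_frac
  proj_pre <- f %*% t(truth$early_axis)
  proj_pre[!is_face, ] <- ogf * (f %*% t(truth$object_axis))[!is_face, ]
  mu_face <- colMeans(f[is_face, , drop = FALSE])
  offset_frac <- if (is.null(truth$late_offset_frac)) 1 else truth$late_offset_frac
  proj_post <- sweep(f, 2, mu_face) %*% t(truth$late_face_axis) +
    rep(offset_frac * as.vector(truth$early_axis %*% mu_face),
        each = nrow(f))
  proj_post[!is_face, ] <- proj_pre[!is_face, ]

  # switch weight over time (0 = early code, 1 = late code)
  w <- as.numeric(time_ms >= truth$switch_time_ms)
  if (crossfade_ms > 0) {
    ramp <- (time_ms - (truth$switch_time_ms - crossfade_ms / 2)) / crossfade_ms
    w <- pmin(pmax(ramp, 0), 1)
  }

  rates <- array(0, dim = c(n_cells, n_stim, Tn))
  with_seed(seed, {
    visual <- if (is.null(truth$visual_drive_hz)) rep(0, n_cells) else
      truth$visual_drive_hz
    for (j in seq_len(n_cells)) {
      k_t <- resp_kernel(time_ms - truth$latency_ms[j])
      drive <- outer(proj_pre[, j], k_t * (1 - w)) +
        outer(proj_post[, j], k_t * w)
      m <- truth$baseline_hz[j] + truth$gain_hz[j] * drive +
        rep(visual[j] * k_t, each = n_stim)
      if (noise_model == "none") m <- pmax(m, 0)
      rates[j, , ] <- apply_rate_noise(m, noise_model, truth$noise_sd, n_repeats)
    }
  })
  new_response_tensor(rates, time_ms, n_repeats, stimuli$category, stimuli$ids)
}

#' Rectified single-axis model responses with a raised threshold
#'
#' The response of a model cell encoding a single axis under an optional
#' raised firing threshold: `rate = max(0, <axis, f> - threshold)`. Used to
#' test whether thresholding alone (cell-intrinsic adaptation) can masquerade
#' as an axis change — it cannot.
#'
#' @param axis K-vector encoding axis.
#' @param stimuli A `stimulus_set`.
#' @param threshold Non-negative threshold subtracted before rectification.
#' @return Numeric vector of per-stimulus rates.
#' @export
threshold_model_responses <- function(axis, stimuli, threshold = 0) {
  stopifnot(threshold >= 0)
  f <- stimuli$embeddings[, seq_along(axis), drop = FALSE]
  pmax(as.vector(f %*% axis) - threshold, 0)
}

# ---- cell-intrinsic artifact generators (control scenarios) ----------------

single_axis_truth <- function(stimuli, K, n_cells, seed, gain_hz = 40,
                              baseline_hz = 5, noise_model = "poisson",
                              noise_sd = 30) {
  make_no_switch_truth(K = K, n_cells = n_cells, gain_hz = gain_hz,
                       baseline_hz = baseline_hz, noise_model = noise_model,
                       noise_sd = noise_sd, seed = seed)
}

#' Cell-intrinsic artifact populations
#'
#' Three generators emulating hypothetical single-axis mechanisms that could
#' be mistaken for an axis switch, used as negative controls for the reversal
#' detectors:
#'
#' * `simulate_gain_artifact()`: fixed axis, but the gain has a strong early
#'   transient and a weaker sustained phase (high response magnitude without
#'   any code change).
#' * `simulate_latency_artifact()`: fixed axis, but response latency increases
#'   for weakly driving stimuli (delayed weak responses), so late windows
#'   over-represent weak stimuli.
#' * `simulate_threshold_artifact()`: fixed axis with a raised firing
#'   threshold switched on after `onset_ms` (adaptation after the transient).
#'
#' All three keep every cell's encoding axis constant; reversal detectors run
#' on their output must stay silent.
#'
#' @param stimuli A `stimulus_set`.
#' @param K Axis dimensionality.
#' @param n_cells Number of cells.
#' @param time_ms,n_repeats As in [simulate_population()].
#' @param transient_gain Ratio of early transient gain to sustained gain
#'   (gain artifact).
#' @param latency_slope_ms Extra latency, in ms, for the weakest stimulus
#'   relative to the strongest (latency artifact).
#' @param threshold_hz,onset_ms Raised threshold in Hz and the time it
#'   engages (threshold artifact).
#' @param seed Integer seed.
#' @return A `response_tensor` with the generating `ground_truth` attached as
#'   attribute `"truth"`.
#' @name artifact_populations
NULL

#' @rdname artifact_populations
#' @export
simulate_gain_artifact <- function(stimuli, K = 60, n_cells = 50,
                                   time_ms = -50:299, n_repeats = 10,
                                   transient_gain = 3, seed = 1) {
  truth <- single_axis_truth(stimuli, K, n_cells, seed)
  f <- stimuli$embeddings[, seq_len(K), drop = FALSE]
  proj <- f %*% t(truth$early_axis)
  Tn <- length(time_ms)
  rates <- array(0, dim = c(n_cells, nrow(f), Tn))
  with_seed(seed + 1L, {
    for (j in seq_len(n_cells)) {
      tt <- time_ms - truth$latency_ms[j]
      # transient component decays fast, sustained component persists
      k_t <- transient_gain * resp_kernel(tt, rise_ms = 5, decay_ms = 25) +
        resp_kernel(tt, rise_ms = 10, decay_ms = 120)
      m <- truth$baseline_hz[j] + truth$gain_hz[j] * outer(proj[, j], k_t)
      rates[j, , ] <- apply_rate_noise(m, truth$noise_model, truth$noise_sd,
                                       n_repeats)
    }
  })
  out <- new_response_tensor(rates, time_ms, n_repeats, stimuli$category,
                             stimuli$ids)
  attr(out, "truth") <- truth
  out
}

#' @rdname artifact_populations
#' @export
simulate_latency_artifact <- function(stimuli, K = 60, n_cells = 50,
                                      time_ms = -50:299, n_repeats = 10,
                                      latency_slope_ms = 60, seed = 1) {
  truth <- single_axis_truth(stimuli, K, n_cells, seed)
  f <- stimuli$embeddings[, seq_len(K), drop = FALSE]
  proj <- f %*% t(truth$early_axis)
  Tn <- length(time_ms)
  rates <- array(0, dim = c(n_cells, nrow(f), Tn))
  with_seed(seed + 1L, {
    for (j in seq_len(n_cells)) {
      p <- proj[, j]
      # weaker (smaller-projection) stimuli respond later
      rel <- (max(p) - p) / max(max(p) - min(p), 1e-12)
      lat <- truth$latency_ms[j] + latency_slope_ms * rel
      m <- matrix(0, nrow(f), Tn)
      for (i in seq_len(nrow(f))) {
        m[i, ] <- truth$baseline_hz[j] +
          truth$gain_hz[j] * p[i] * resp_kernel(time_ms - lat[i])
      }
      rates[j, , ] <- apply_rate_noise(m, truth$noise_model, truth$noise_sd,
                                       n_repeats)
    }
  })
  out <- new_response_tensor(rates, time_ms, n_repeats, stimuli$category,
                             stimuli$ids)
  attr(out, "truth") <- truth
  out
}

#' @rdname artifact_populations
#' @export
simulate_threshold_artifact <- function(stimuli, K = 60, n_cells = 50,
                                        time_ms = -50:299, n_repeats = 10,
                                        threshold_hz = 10, onset_ms = 110,
                                        seed = 1) {
  truth <- single_axis_truth(stimuli, K, n_cells, seed)
  f <- stimuli$embeddings[, seq_len(K), drop = FALSE]
  proj <- f %*% t(truth$early_axis)
  Tn <- length(time_ms)
  rates <- array(0, dim = c(n_cells, nrow(f), Tn))
  theta <- ifelse(time_ms >= onset_ms, threshold_hz, 0)
  with_seed(seed + 1L, {
    for (j in seq_len(n_cells)) {
      k_t <- resp_kernel(time_ms - truth$latency_ms[j])
      drive <- truth$gain_hz[j] * outer(proj[, j], k_t)
      m <- truth$baseline_hz[j] +
        pmax(sweep(drive, 2, theta, "-"), -truth$baseline_hz[j])
      rates[j, , ] <- apply_rate_noise(m, truth$noise_model, truth$noise_sd,
                                       n_repeats)
    }
  })
  out <- new_response_tensor(rates, time_ms, n_repeats, stimuli$category,
                             stimuli$ids)
  attr(out, "truth") <- truth
  out
}

#' Mean rates per stimulus in a time window
#'
#' @param pop A `response_tensor`.
#' @param window `[start, end)` window in ms.
#' @return cells x stimuli matrix of window-mean rates.
#' @export
window_mean_rates <- function(pop, window) {
  idx <- which(pop$time_ms >= window[1] & pop$time_ms < window[2])
  if (length(idx) == 0) abort("window contains no time bins")
  out <- rowSums(pop$rates[, , idx, drop = FALSE], dims = 2) / length(idx)
  dimnames(out) <- list(pop$cell_ids, pop$ids)
  out
}
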